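// GLPK-backed solvers for flux balance analysis.
//
// All problems share the structure  max c'v  s.t.  S v = 0,  lb <= v <= ub
// with finite bounds throughout (irreversible reactions have lb = 0, exchanges
// use finite uptake/secretion bounds), so v = 0 is feasible whenever no lower
// bound is strictly positive and infeasibility only arises through imposed
// biomass minima.

#include <Rcpp.h>
#include <glpk.h>
#include <vector>

using namespace Rcpp;

namespace {

struct GlpkProblem {
  glp_prob *lp;
  GlpkProblem() : lp(glp_create_prob()) { glp_term_out(GLP_OFF); }
  ~GlpkProblem() { glp_delete_prob(lp); }
};

void set_col_bounds(glp_prob *lp, int j, double lo, double hi) {
  if (lo == hi)
    glp_set_col_bnds(lp, j, GLP_FX, lo, hi);
  else
    glp_set_col_bnds(lp, j, GLP_DB, lo, hi);
}

// Build rows (mass balance, all fixed at 0), columns and the constraint matrix.
void load_problem(glp_prob *lp, int n_mets, int n_rxns,
                  const IntegerVector &si, const IntegerVector &sj,
                  const NumericVector &sx, const NumericVector &lb,
                  const NumericVector &ub) {
  glp_add_rows(lp, n_mets);
  for (int i = 1; i <= n_mets; ++i) glp_set_row_bnds(lp, i, GLP_FX, 0.0, 0.0);
  glp_add_cols(lp, n_rxns);
  for (int j = 1; j <= n_rxns; ++j) set_col_bounds(lp, j, lb[j - 1], ub[j - 1]);
  int ne = si.size();
  std::vector<int> ia(ne + 1), ja(ne + 1);
  std::vector<double> ar(ne + 1);
  for (int k = 0; k < ne; ++k) {
    ia[k + 1] = si[k];
    ja[k + 1] = sj[k];
    ar[k + 1] = sx[k];
  }
  glp_load_matrix(lp, ne, ia.data(), ja.data(), ar.data());
}

double solve_current(glp_prob *lp, glp_smcp *parm, bool *failed) {
  int rc = glp_simplex(lp, parm);
  int st = glp_get_status(lp);
  if (rc != 0 || (st != GLP_OPT && st != GLP_NOFEAS && st != GLP_INFEAS)) {
    // retry from a fresh standard basis before declaring failure
    glp_std_basis(lp);
    rc = glp_simplex(lp, parm);
    st = glp_get_status(lp);
  }
  if (rc == 0 && st == GLP_OPT) return glp_get_obj_val(lp);
  if (rc == 0 && (st == GLP_NOFEAS || st == GLP_INFEAS)) return 0.0;
  *failed = true;
  return NA_REAL;
}

} // namespace

// Solve one FBA LP per genotype, reusing the factorised basis between solves.
// `genotypes` has one row per genotype and one 0/1 column per entry of
// `internal_cols` (1-based column indices into the stoichiometric matrix);
// a 0 bit fixes the corresponding flux to zero.
// [[Rcpp::export(name = ".fba_batch_cpp")]]
NumericVector fba_batch_cpp(int n_mets, int n_rxns, IntegerVector si,
                            IntegerVector sj, NumericVector sx,
                            NumericVector lb, NumericVector ub, int obj_col,
                            IntegerVector internal_cols,
                            IntegerMatrix genotypes) {
  GlpkProblem prob;
  glp_set_obj_dir(prob.lp, GLP_MAX);
  load_problem(prob.lp, n_mets, n_rxns, si, sj, sx, lb, ub);
  glp_set_obj_coef(prob.lp, obj_col, 1.0);

  glp_smcp parm;
  glp_init_smcp(&parm);
  parm.msg_lev = GLP_MSG_OFF;

  int ng = genotypes.nrow(), nb = internal_cols.size();
  NumericVector out(ng);
  bool failed = false;
  for (int g = 0; g < ng; ++g) {
    for (int k = 0; k < nb; ++k) {
      int j = internal_cols[k];
      if (genotypes(g, k) == 0)
        glp_set_col_bnds(prob.lp, j, GLP_FX, 0.0, 0.0);
      else
        set_col_bounds(prob.lp, j, lb[j - 1], ub[j - 1]);
    }
    out[g] = solve_current(prob.lp, &parm, &failed);
    if (failed) stop("GLPK simplex failed with a non-optimal status");
    if (g % 4096 == 4095) checkUserInterrupt();
  }
  return out;
}

// Flux variability: min and max feasible flux for each column in `scan_cols`
// under mass balance and bounds alone (optionally with a minimum flux imposed
// on `floor_col`, e.g. a biomass floor).
// [[Rcpp::export(name = ".fva_cpp")]]
NumericMatrix fva_cpp(int n_mets, int n_rxns, IntegerVector si,
                      IntegerVector sj, NumericVector sx, NumericVector lb,
                      NumericVector ub, IntegerVector scan_cols, int floor_col,
                      double floor_value) {
  GlpkProblem prob;
  load_problem(prob.lp, n_mets, n_rxns, si, sj, sx, lb, ub);
  if (floor_col > 0)
    set_col_bounds(prob.lp, floor_col,
                   std::max(lb[floor_col - 1], floor_value), ub[floor_col - 1]);

  glp_smcp parm;
  glp_init_smcp(&parm);
  parm.msg_lev = GLP_MSG_OFF;

  int ns = scan_cols.size();
  NumericMatrix out(ns, 2);
  bool failed = false;
  for (int k = 0; k < ns; ++k) {
    int j = scan_cols[k];
    glp_set_obj_coef(prob.lp, j, 1.0);
    glp_set_obj_dir(prob.lp, GLP_MIN);
    out(k, 0) = solve_current(prob.lp, &parm, &failed);
    glp_set_obj_dir(prob.lp, GLP_MAX);
    out(k, 1) = solve_current(prob.lp, &parm, &failed);
    glp_set_obj_coef(prob.lp, j, 0.0);
    if (failed) stop("GLPK simplex failed during flux variability scan");
  }
  return out;
}

// Minimal number of internal reactions supporting viability in every listed
// environment simultaneously.  Layout: one flux-vector copy per environment
// followed by one binary presence variable per internal reaction.  Flux bounds
// differ per environment (columns of env_lb/env_ub); viability is imposed as a
// lower bound on each environment's biomass flux.  Big-M coupling rows tie
// fluxes to the shared binaries.
// [[Rcpp::export(name = ".milp_min_reactions_cpp")]]
List milp_min_reactions_cpp(int n_mets, int n_rxns, IntegerVector si,
                            IntegerVector sj, NumericVector sx,
                            NumericMatrix env_lb, NumericMatrix env_ub,
                            int obj_col, NumericVector biomass_floor,
                            IntegerVector internal_cols,
                            IntegerVector forced_on, int upper_bound,
                            double time_limit_s) {
  int ne = env_lb.ncol(), nb = internal_cols.size();
  int ncols = ne * n_rxns + nb;

  GlpkProblem prob;
  glp_prob *lp = prob.lp;
  glp_set_obj_dir(lp, GLP_MIN);
  glp_add_cols(lp, ncols);

  for (int e = 0; e < ne; ++e)
    for (int j = 0; j < n_rxns; ++j) {
      int col = e * n_rxns + j + 1;
      double lo = env_lb(j, e), hi = env_ub(j, e);
      if (j + 1 == obj_col) lo = std::max(lo, biomass_floor[e]);
      set_col_bounds(lp, col, lo, hi);
    }
  for (int k = 0; k < nb; ++k) {
    int col = ne * n_rxns + k + 1;
    glp_set_col_kind(lp, col, GLP_BV);
    glp_set_obj_coef(lp, col, 1.0);
  }
  for (int k = 0; k < forced_on.size(); ++k) {
    int col = ne * n_rxns + forced_on[k];
    glp_set_col_bnds(lp, col, GLP_FX, 1.0, 1.0);
  }

  int nrows = ne * n_mets + ne * 2 * nb + (upper_bound > 0 ? 1 : 0);
  glp_add_rows(lp, nrows);
  std::vector<int> ia(1), ja(1);
  std::vector<double> ar(1);

  int row = 0;
  // mass balance per environment copy
  for (int e = 0; e < ne; ++e)
    for (int i = 0; i < n_mets; ++i) glp_set_row_bnds(lp, ++row, GLP_FX, 0.0, 0.0);
  for (int k = 0; k < si.size(); ++k)
    for (int e = 0; e < ne; ++e) {
      ia.push_back(e * n_mets + si[k]);
      ja.push_back(e * n_rxns + sj[k]);
      ar.push_back(sx[k]);
    }
  // coupling: v_ej - ub_ej y_j <= 0  and  v_ej - lb_ej y_j >= 0
  for (int e = 0; e < ne; ++e)
    for (int k = 0; k < nb; ++k) {
      int j = internal_cols[k];
      int vcol = e * n_rxns + j, ycol = ne * n_rxns + k + 1;
      glp_set_row_bnds(lp, ++row, GLP_UP, 0.0, 0.0);
      ia.push_back(row); ja.push_back(vcol); ar.push_back(1.0);
      ia.push_back(row); ja.push_back(ycol); ar.push_back(-env_ub(j - 1, e));
      glp_set_row_bnds(lp, ++row, GLP_LO, 0.0, 0.0);
      ia.push_back(row); ja.push_back(vcol); ar.push_back(1.0);
      ia.push_back(row); ja.push_back(ycol); ar.push_back(-env_lb(j - 1, e));
    }
  if (upper_bound > 0) {
    glp_set_row_bnds(lp, ++row, GLP_UP, 0.0, (double)upper_bound);
    for (int k = 0; k < nb; ++k) {
      ia.push_back(row);
      ja.push_back(ne * n_rxns + k + 1);
      ar.push_back(1.0);
    }
  }
  glp_load_matrix(lp, (int)ia.size() - 1, ia.data(), ja.data(), ar.data());

  glp_iocp iparm;
  glp_init_iocp(&iparm);
  iparm.msg_lev = GLP_MSG_OFF;
  iparm.presolve = GLP_ON;
  iparm.binarize = GLP_ON;
  // default tol_int (1e-5) lets near-zero binaries leak up to M * 1e-5 of
  // flux through the big-M couplings, enough to clear a 1% biomass floor
  iparm.tol_int = 1e-9;
  if (time_limit_s > 0) iparm.tm_lim = (int)(time_limit_s * 1000.0);
  int rc = glp_intopt(lp, &iparm);
  int st = glp_mip_status(lp);

  std::string status;
  if (rc == 0 && st == GLP_OPT) status = "optimal";
  else if (rc == GLP_ETMLIM) status = "time_limit";
  else if (st == GLP_NOFEAS) status = "infeasible";
  else if (st == GLP_FEAS) status = "feasible";
  else status = "failed";

  IntegerVector witness(nb, NA_INTEGER);
  double obj = NA_REAL;
  if (st == GLP_OPT || st == GLP_FEAS) {
    obj = glp_mip_obj_val(lp);
    for (int k = 0; k < nb; ++k)
      witness[k] = (int)(glp_mip_col_val(lp, ne * n_rxns + k + 1) + 0.5);
  }
  return List::create(_["size"] = obj, _["witness"] = witness,
                      _["status"] = status);
}
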