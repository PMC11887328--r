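#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Felsenstein pruning for a two-state model with a discrete rate mixture.
//
// edge      : E x 2 integer matrix of (parent, child) node ids (1-based),
//             ordered so every child row precedes any row using it as parent
//             (ape "postorder").
// P         : numeric vector of per-edge, per-category 2x2 transition
//             matrices, laid out P[e*ncat*4 + c*4 + 2*x + y] = P_xy.
// tipstate  : npat x ntip integer matrix of 0/1 states; column t is the
//             state of tree tip t (node id t+1 in 0-based terms).
// weight    : npat pattern multiplicities.
// pi        : stationary frequencies (pi0, pi1).
// catw      : mixture weights of the ncat categories.
// nnode     : total number of nodes (tips + internals).
// root      : root node id (1-based).
//
// Returns total log-likelihood and per-pattern site log-likelihoods.
// A pattern with zero likelihood yields -Inf, propagated to the total.
// [[Rcpp::export]]
List loglik_bin_cpp(IntegerMatrix edge, NumericVector P, IntegerMatrix tipstate,
                    NumericVector weight, NumericVector pi, NumericVector catw,
                    int nnode, int root) {
  int E = edge.nrow();
  int ncat = catw.size();
  int npat = tipstate.nrow();
  int ntip = tipstate.ncol();

  std::vector<double> sitelik(npat, 0.0);
  // partials: nnode x npat x 2, reset per category
  std::vector<double> part((size_t)nnode * npat * 2);

  for (int c = 0; c < ncat; ++c) {
    std::fill(part.begin(), part.end(), 1.0);
    for (int t = 0; t < ntip; ++t) {
      double *p = &part[(size_t)t * npat * 2];
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(s, t);
        p[2 * s] = (st == 0) ? 1.0 : 0.0;
        p[2 * s + 1] = (st == 1) ? 1.0 : 0.0;
      }
    }
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const double *Pe = &P[(size_t)e * ncat * 4 + (size_t)c * 4];
      double *pp = &part[(size_t)par * npat * 2];
      const double *pc = &part[(size_t)ch * npat * 2];
      for (int s = 0; s < npat; ++s) {
        double l0 = pc[2 * s], l1 = pc[2 * s + 1];
        pp[2 * s] *= Pe[0] * l0 + Pe[1] * l1;
        pp[2 * s + 1] *= Pe[2] * l0 + Pe[3] * l1;
      }
    }
    const double *pr = &part[(size_t)(root - 1) * npat * 2];
    double w = catw[c];
    for (int s = 0; s < npat; ++s)
      sitelik[s] += w * (pi[0] * pr[2 * s] + pi[1] * pr[2 * s + 1]);
  }

  NumericVector slog(npat);
  double total = 0.0;
  for (int s = 0; s < npat; ++s) {
    slog[s] = std::log(sitelik[s]);
    total += weight[s] * slog[s];
  }
  return List::create(_["loglik"] = total, _["site_loglik"] = slog);
}

// Inside/outside partials for one target edge, so a branch length can be
// optimized with O(npat) work per candidate value: the site likelihood
// factorizes as sum_{x,y} out[x] * P_xy(t) * below[y] for every category.
//
// Returns `below` (partials of the child subtree) and `out` (partials of
// everything outside the edge, stationary frequencies folded in), each
// laid out [cat][state][pattern] as an npat x 2 x ncat array.
// [[Rcpp::export]]
List edge_partials_cpp(IntegerMatrix edge, NumericVector P,
                       IntegerMatrix tipstate, NumericVector pi,
                       int ncat, int nnode, int root, int target) {
  int E = edge.nrow();
  int npat = tipstate.nrow();
  int ntip = tipstate.ncol();
  int t0 = target - 1;

  std::vector<int> par_edge(nnode, -1); // incoming edge per node
  for (int e = 0; e < E; ++e) par_edge[edge(e, 1) - 1] = e;

  NumericVector below_out(npat * 2 * ncat), out_out(npat * 2 * ncat);
  std::vector<double> part((size_t)nnode * npat * 2);
  std::vector<double> M((size_t)npat * 2); // edge message toward the root
  std::vector<double> U((size_t)npat * 2), Unext((size_t)npat * 2);

  for (int c = 0; c < ncat; ++c) {
    std::fill(part.begin(), part.end(), 1.0);
    for (int t = 0; t < ntip; ++t) {
      double *p = &part[(size_t)t * npat * 2];
      for (int s = 0; s < npat; ++s) {
        int st = tipstate(s, t);
        p[2 * s] = (st == 0) ? 1.0 : 0.0;
        p[2 * s + 1] = (st == 1) ? 1.0 : 0.0;
      }
    }
    for (int e = 0; e < E; ++e) {
      int parn = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const double *Pe = &P[(size_t)e * ncat * 4 + (size_t)c * 4];
      double *pp = &part[(size_t)parn * npat * 2];
      const double *pc = &part[(size_t)ch * npat * 2];
      for (int s = 0; s < npat; ++s) {
        double l0 = pc[2 * s], l1 = pc[2 * s + 1];
        pp[2 * s] *= Pe[0] * l0 + Pe[1] * l1;
        pp[2 * s + 1] *= Pe[2] * l0 + Pe[3] * l1;
      }
    }
    // below partial of the target edge's child
    {
      int ch = edge(t0, 1) - 1;
      const double *pc = &part[(size_t)ch * npat * 2];
      for (int s = 0; s < npat; ++s) {
        below_out[c * npat * 2 + s] = pc[2 * s];
        below_out[c * npat * 2 + npat + s] = pc[2 * s + 1];
      }
    }
    // path from root down to the target edge's parent node
    std::vector<int> path; // edges from just below root down to parent(target)
    for (int node = edge(t0, 0) - 1; node != root - 1;) {
      int pe = par_edge[node];
      path.push_back(pe);
      node = edge(pe, 0) - 1;
    }
    std::reverse(path.begin(), path.end());
    for (int s = 0; s < npat; ++s) {
      U[2 * s] = pi[0];
      U[2 * s + 1] = pi[1];
    }
    int cur_node = root - 1;
    auto mult_siblings = [&](int at_node, int skip_edge) {
      // multiply U by the messages of all at_node's child edges except
      // skip_edge (and except the path continuation handled elsewhere)
      for (int e = 0; e < E; ++e) {
        if (edge(e, 0) - 1 != at_node || e == skip_edge) continue;
        const double *Pe = &P[(size_t)e * ncat * 4 + (size_t)c * 4];
        const double *pc = &part[(size_t)(edge(e, 1) - 1) * npat * 2];
        for (int s = 0; s < npat; ++s) {
          double l0 = pc[2 * s], l1 = pc[2 * s + 1];
          U[2 * s] *= Pe[0] * l0 + Pe[1] * l1;
          U[2 * s + 1] *= Pe[2] * l0 + Pe[3] * l1;
        }
      }
    };
    for (int pe : path) {
      // descend along path edge pe: fold in cur_node's other children,
      // then push U through pe
      mult_siblings(cur_node, pe);
      const double *Pe = &P[(size_t)pe * ncat * 4 + (size_t)c * 4];
      for (int s = 0; s < npat; ++s) {
        double u0 = U[2 * s], u1 = U[2 * s + 1];
        Unext[2 * s] = Pe[0] * u0 + Pe[2] * u1;
        Unext[2 * s + 1] = Pe[1] * u0 + Pe[3] * u1;
      }
      std::swap(U, Unext);
      cur_node = edge(pe, 1) - 1;
    }
    // at the target's parent: fold in its other children
    mult_siblings(cur_node, t0);
    for (int s = 0; s < npat; ++s) {
      out_out[c * npat * 2 + s] = U[2 * s];
      out_out[c * npat * 2 + npat + s] = U[2 * s + 1];
    }
  }
  return List::create(_["below"] = below_out, _["out"] = out_out);
}

// Log-likelihood as a function of one edge's transition probabilities,
// given that edge's inside/outside partials (from edge_partials_cpp).
// p4 holds (P00, P01, P10, P11) per category.
// [[Rcpp::export]]
double edge_loglik_cpp(NumericVector below, NumericVector out,
                       NumericVector p4, NumericVector weight,
                       NumericVector catw) {
  int ncat = catw.size();
  int npat = weight.size();
  double total = 0.0;
  std::vector<double> site(npat, 0.0);
  for (int c = 0; c < ncat; ++c) {
    const double *b0 = &below[c * npat * 2], *b1 = b0 + npat;
    const double *a0 = &out[c * npat * 2], *a1 = a0 + npat;
    double P00 = p4[4 * c], P01 = p4[4 * c + 1];
    double P10 = p4[4 * c + 2], P11 = p4[4 * c + 3];
    double w = catw[c];
    for (int s = 0; s < npat; ++s)
      site[s] += w * (a0[s] * (P00 * b0[s] + P01 * b1[s]) +
                      a1[s] * (P10 * b0[s] + P11 * b1[s]));
  }
  for (int s = 0; s < npat; ++s) total += weight[s] * std::log(site[s]);
  return total;
}
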