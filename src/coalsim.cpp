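// Structured-coalescent simulation core.
//
// Demographies are compiled in R (see R/demography.R) into flat arrays:
// a merge schedule (pairs of demes joining into an ancestral deme, in
// increasing time order) and a tiling of [0, root_time] into migration
// epochs, each with a full backward per-generation migration-rate matrix.
// Times are in generations; deme sizes are diploid N_e, so k lineages in a
// deme of size N coalesce at rate k(k-1)/(4N) per generation.
//
// All randomness goes through R's RNG so set.seed() in R controls replay.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SimTree {
  int n;                         // tip count
  std::vector<int> parent;       // 0-based node index, -1 at root; size 2n-1
  std::vector<double> time;      // node times, tips at 0
  // internal nodes occupy indices n .. 2n-2 in order of creation (time order)
};

// One realization of the structured coalescent. tipDeme is 0-based.
SimTree simulate_tree(const IntegerVector& tipDeme,
                      int nDemes,
                      const NumericVector& N,
                      const NumericVector& mergeTime,
                      const IntegerVector& mergeA,
                      const IntegerVector& mergeB,
                      const IntegerVector& mergeP,
                      const NumericVector& epStart,
                      const NumericVector& epEnd,
                      const List& epM) {
  const int n = tipDeme.size();
  const int nMerge = mergeTime.size();
  const int nEp = epStart.size();

  SimTree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  std::vector<int> lin;      // active lineage node ids
  std::vector<int> linDeme;  // deme of each active lineage
  lin.reserve(n); linDeme.reserve(n);
  for (int i = 0; i < n; ++i) { lin.push_back(i); linDeme.push_back(tipDeme[i]); }

  std::vector<int> k(nDemes, 0);
  for (int i = 0; i < n; ++i) k[tipDeme[i]]++;

  // cache epoch matrices and their row sums
  std::vector<NumericMatrix> M(nEp);
  std::vector<std::vector<double> > rs(nEp);
  for (int e = 0; e < nEp; ++e) {
    M[e] = as<NumericMatrix>(epM[e]);
    rs[e].assign(nDemes, 0.0);
    for (int i = 0; i < nDemes; ++i) {
      double s = 0.0;
      for (int j = 0; j < nDemes; ++j) if (j != i) s += M[e](i, j);
      rs[e][i] = s;
    }
  }

  double t = 0.0;
  int mergeIdx = 0, created = 0;
  int nLin = n;

  // apply any merges scheduled at time 0 immediately
  while (mergeIdx < nMerge && mergeTime[mergeIdx] <= 0.0) {
    int a = mergeA[mergeIdx], b = mergeB[mergeIdx], p = mergeP[mergeIdx];
    for (int i = 0; i < nLin; ++i)
      if (linDeme[i] == a || linDeme[i] == b) linDeme[i] = p;
    k[p] += k[a] + k[b]; k[a] = 0; k[b] = 0;
    ++mergeIdx;
  }

  long guard = 0;
  const long guardMax = 100000000L;

  while (nLin > 1) {
    if (++guard > guardMax) stop("coalescent simulation failed to finish (rate starvation?)");

    // current epoch (if any)
    int ep = -1;
    for (int e = 0; e < nEp; ++e) {
      if (t >= epStart[e] - 1e-12 && t < epEnd[e] - 1e-12) { ep = e; break; }
    }

    double coalRate = 0.0;
    for (int i = 0; i < nDemes; ++i)
      if (k[i] > 1) coalRate += (double)k[i] * (k[i] - 1) / (4.0 * N[i]);
    double migRate = 0.0;
    if (ep >= 0)
      for (int i = 0; i < nDemes; ++i)
        if (k[i] > 0) migRate += k[i] * rs[ep][i];
    double tot = coalRate + migRate;

    double boundary = R_PosInf;
    if (mergeIdx < nMerge) boundary = mergeTime[mergeIdx];
    if (ep >= 0 && epEnd[ep] < boundary) boundary = epEnd[ep];
    else if (ep < 0) {
      // maybe a future epoch starts later
      for (int e = 0; e < nEp; ++e)
        if (epStart[e] > t && epStart[e] < boundary) boundary = epStart[e];
    }

    double tNew;
    if (tot <= 0.0) {
      tNew = boundary;
      if (!R_FINITE(tNew))
        stop("no coalescence possible: zero total rate with no pending events");
    } else {
      tNew = t + exp_rand() / tot;
    }

    if (tNew >= boundary) {
      t = boundary;
      if (mergeIdx < nMerge && boundary == mergeTime[mergeIdx]) {
        int a = mergeA[mergeIdx], b = mergeB[mergeIdx], p = mergeP[mergeIdx];
        for (int i = 0; i < nLin; ++i)
          if (linDeme[i] == a || linDeme[i] == b) linDeme[i] = p;
        k[p] += k[a] + k[b]; k[a] = 0; k[b] = 0;
        ++mergeIdx;
      }
      // epoch transitions are implicit (recomputed at loop head)
      continue;
    }

    t = tNew;
    double u = unif_rand() * tot;
    if (u < coalRate) {
      // choose deme
      double acc = 0.0; int d = -1;
      for (int i = 0; i < nDemes; ++i) {
        if (k[i] > 1) {
          acc += (double)k[i] * (k[i] - 1) / (4.0 * N[i]);
          if (u < acc) { d = i; break; }
        }
      }
      if (d < 0) d = nDemes - 1;
      // choose two distinct lineages in deme d
      int c1 = (int)(unif_rand() * k[d]); if (c1 >= k[d]) c1 = k[d] - 1;
      int c2 = (int)(unif_rand() * (k[d] - 1)); if (c2 >= k[d] - 1) c2 = k[d] - 2;
      if (c2 >= c1) ++c2;
      // map within-deme ranks to lineage indices
      int i1 = -1, i2 = -1, seen = 0;
      for (int i = 0; i < nLin; ++i) {
        if (linDeme[i] == d) {
          if (seen == c1) i1 = i;
          if (seen == c2) i2 = i;
          ++seen;
        }
      }
      int node = n + created; ++created;
      tr.time[node] = t;
      tr.parent[lin[i1]] = node;
      tr.parent[lin[i2]] = node;
      lin[i1] = node; // replaces first child
      lin[i2] = lin[nLin - 1]; linDeme[i2] = linDeme[nLin - 1];
      --nLin; lin.resize(nLin); linDeme.resize(nLin);
      k[d]--;
    } else {
      // migration
      double v = u - coalRate;
      double acc = 0.0; int d = -1;
      for (int i = 0; i < nDemes; ++i) {
        if (k[i] > 0 && rs[ep][i] > 0) {
          acc += k[i] * rs[ep][i];
          if (v < acc) { d = i; break; }
        }
      }
      if (d < 0) continue; // numerical edge: no-op
      int c = (int)(unif_rand() * k[d]); if (c >= k[d]) c = k[d] - 1;
      int il = -1, seen = 0;
      for (int i = 0; i < nLin; ++i)
        if (linDeme[i] == d) { if (seen == c) { il = i; break; } ++seen; }
      double w = unif_rand() * rs[ep][d], acc2 = 0.0;
      int dest = -1;
      for (int j = 0; j < nDemes; ++j) {
        if (j == d) continue;
        acc2 += M[ep](d, j);
        if (w < acc2) { dest = j; break; }
      }
      if (dest < 0) continue;
      linDeme[il] = dest;
      k[d]--; k[dest]++;
    }
  }
  return tr;
}

// Convert a SimTree into ape-style pieces: tips 1..n, internal nodes
// renumbered so the root (last created) is n+1 and earlier nodes count up
// from 2n-1 downward (decreasing time with increasing id beyond the root).
List tree_to_ape(const SimTree& tr) {
  const int n = tr.n;
  const int nNode = n - 1;
  std::vector<int> newId(2 * n - 1);
  for (int i = 0; i < n; ++i) newId[i] = i + 1;
  for (int c = 0; c < nNode; ++c) newId[n + c] = 2 * n - 1 - c; // last created -> n+1
  IntegerMatrix edge(2 * n - 2, 2);
  NumericVector edgeLen(2 * n - 2);
  NumericVector nodeTime(2 * n - 1);
  for (int i = 0; i < 2 * n - 1; ++i) nodeTime[newId[i] - 1] = tr.time[i];
  int e = 0;
  for (int i = 0; i < 2 * n - 1; ++i) {
    if (tr.parent[i] < 0) continue;
    edge(e, 0) = newId[tr.parent[i]];
    edge(e, 1) = newId[i];
    edgeLen[e] = tr.time[tr.parent[i]] - tr.time[i];
    ++e;
  }
  return List::create(_["edge"] = edge, _["edge.length"] = edgeLen,
                      _["Nnode"] = nNode, _["node.time"] = nodeTime);
}

// Pairwise mutation-count distances given per-node edge mutation counts
// (count on the edge above each node; root 0). O(n^2) subtree sweep.
NumericMatrix pair_dist(const SimTree& tr, const std::vector<double>& cnt) {
  const int n = tr.n;
  std::vector<double> cum(2 * n - 1, 0.0);
  // root is last created internal node (n + n - 2)
  // process nodes in decreasing time: internal creation order reversed, then tips
  for (int c = n - 3; c >= 0; --c) {
    int node = n + c;
    cum[node] = cum[tr.parent[node]] + cnt[node];
  }
  for (int i = 0; i < n; ++i) cum[i] = cum[tr.parent[i]] + cnt[i];

  std::vector<std::vector<int> > tipset(2 * n - 1);
  for (int i = 0; i < n; ++i) tipset[i].push_back(i);
  std::vector<std::vector<int> > kids(2 * n - 1);
  for (int i = 0; i < 2 * n - 2; ++i)
    if (tr.parent[i] >= 0) kids[tr.parent[i]].push_back(i);
  if (tr.parent[2 * n - 2] >= 0) kids[tr.parent[2 * n - 2]].push_back(2 * n - 2);

  NumericMatrix D(n, n);
  for (int c = 0; c < n - 1; ++c) {
    int v = n + c;
    const std::vector<int>& ch = kids[v];
    // distances across the two child subtrees
    for (size_t x = 0; x < ch.size(); ++x)
      for (size_t y = x + 1; y < ch.size(); ++y)
        for (size_t a = 0; a < tipset[ch[x]].size(); ++a)
          for (size_t b = 0; b < tipset[ch[y]].size(); ++b) {
            int ta = tipset[ch[x]][a], tb = tipset[ch[y]][b];
            double d = cum[ta] + cum[tb] - 2.0 * cum[v];
            D(ta, tb) = d; D(tb, ta) = d;
          }
    for (size_t x = 0; x < ch.size(); ++x) {
      tipset[v].insert(tipset[v].end(), tipset[ch[x]].begin(), tipset[ch[x]].end());
      std::vector<int>().swap(tipset[ch[x]]);
    }
  }
  return D;
}

} // namespace

// [[Rcpp::export(name = ".sim_coal_cpp")]]
List sim_coal_cpp(IntegerVector tipDeme, int nDemes, NumericVector N,
                  NumericVector mergeTime, IntegerVector mergeA,
                  IntegerVector mergeB, IntegerVector mergeP,
                  NumericVector epStart, NumericVector epEnd, List epM) {
  SimTree tr = simulate_tree(tipDeme, nDemes, N, mergeTime, mergeA, mergeB,
                             mergeP, epStart, epEnd, epM);
  return tree_to_ape(tr);
}

// [[Rcpp::export(name = ".sim_locus_dist_cpp")]]
NumericMatrix sim_locus_dist_cpp(IntegerVector tipDeme, int nDemes,
                                 NumericVector N, NumericVector mergeTime,
                                 IntegerVector mergeA, IntegerVector mergeB,
                                 IntegerVector mergeP, NumericVector epStart,
                                 NumericVector epEnd, List epM, double u) {
  SimTree tr = simulate_tree(tipDeme, nDemes, N, mergeTime, mergeA, mergeB,
                             mergeP, epStart, epEnd, epM);
  const int n = tr.n;
  std::vector<double> cnt(2 * n - 1, 0.0);
  for (int i = 0; i < 2 * n - 2; ++i) {
    if (tr.parent[i] < 0) continue;
    double len = tr.time[tr.parent[i]] - tr.time[i];
    cnt[i] = R::rpois(u * len);
  }
  // the (2n-2)-th entry: every node except root has a parent; loop above
  // covers indices 0..2n-3; index 2n-2 is the root itself when created last
  if (tr.parent[2 * n - 2] >= 0) {
    double len = tr.time[tr.parent[2 * n - 2]] - tr.time[2 * n - 2];
    cnt[2 * n - 2] = R::rpois(u * len);
  }
  return pair_dist(tr, cnt);
}

// [[Rcpp::export(name = ".sim_tmrca_cpp")]]
NumericVector sim_tmrca_cpp(IntegerVector tipDeme, int nDemes, NumericVector N,
                            NumericVector mergeTime, IntegerVector mergeA,
                            IntegerVector mergeB, IntegerVector mergeP,
                            NumericVector epStart, NumericVector epEnd,
                            List epM, int nRep) {
  NumericVector out(nRep);
  for (int r = 0; r < nRep; ++r) {
    SimTree tr = simulate_tree(tipDeme, nDemes, N, mergeTime, mergeA, mergeB,
                               mergeP, epStart, epEnd, epM);
    out[r] = tr.time[2 * tr.n - 2];
  }
  return out;
}
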