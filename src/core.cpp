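#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Discrete-Morse sweep over a 2D image.
//
// Pixels are processed in a deterministic total order (value descending,
// linear index ascending). A union-find over processed pixels tracks the
// superlevel-set components; each component carries its peak (the local
// maximum it was born at). A pixel whose processed neighbours span two or
// more components is a merge saddle: the younger peak (lower value) is
// paired with it, giving that peak's persistence. A pixel whose processed
// neighbourhood contains two ring-disconnected arcs of the *same* component
// closes a loop (an H1 saddle) and is recorded separately.
//
// For every saddle event, ridge arcs are traced from the saddle's entry
// neighbours by steepest ascent (move to the neighbour highest in the total
// order) until a local maximum is reached; ascent strictly climbs the order,
// so it terminates and is fully deterministic.

static inline int uf_find(std::vector<int>& par, int x) {
  while (par[x] != x) {
    par[x] = par[par[x]];
    x = par[x];
  }
  return x;
}

// [[Rcpp::export(name = ".morse_sweep")]]
List morse_sweep(NumericMatrix img, double loop_min) {
  const int nr = img.nrow(), nc = img.ncol();
  const long N = (long)nr * nc;
  const double* v = img.begin();

  std::vector<int> order(N);
  for (long i = 0; i < N; ++i) order[i] = (int)i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return v[a] > v[b]; });
  std::vector<int> rank(N);
  for (long i = 0; i < N; ++i) rank[order[i]] = (int)i;

  std::vector<int> par(N, -1);       // -1 = unprocessed
  std::vector<int> peak(N, -1);      // peak pixel of each root
  std::vector<double> pers(N, -1.0); // persistence per peak pixel
  std::vector<int> is_peak(N, 0);

  // ring order of the 8-neighbourhood (circular)
  const int ring_dr[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const int ring_dc[8] = {-1, 0, 1, 1, 1, 0, -1, -1};

  std::vector<int> ev_saddle, ev_entryA, ev_entryB;
  std::vector<int> ev_loop;

  std::vector<int> nb(8), nbrank(8);
  for (long oi = 0; oi < N; ++oi) {
    const int p = order[oi];
    const int pr = p % nr, pc = p / nr;

    int nproc = 0;
    bool ringproc[8];
    int ringpix[8];
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + ring_dr[k], cc = pc + ring_dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) {
        ringproc[k] = false; ringpix[k] = -1; continue;
      }
      const int q = rr + cc * nr;
      ringproc[k] = (par[q] != -1);
      ringpix[k] = q;
      if (ringproc[k]) ++nproc;
    }

    if (nproc == 0) {  // local maximum: new component
      par[p] = p;
      peak[p] = p;
      is_peak[p] = 1;
      continue;
    }

    // attach to the component of the highest-order processed neighbour
    int attach = -1;
    for (int k = 0; k < 8; ++k) {
      if (ringproc[k] && (attach == -1 || rank[ringpix[k]] < rank[attach]))
        attach = ringpix[k];
    }

    // ring groups: maximal circular runs of processed neighbours; for loop
    // detection each group keeps its root and min-rank entry pixel
    int group_of[8];
    int ngroups = 0;
    {
      for (int k = 0; k < 8; ++k) group_of[k] = -1;
      int start = -1;
      for (int k = 0; k < 8; ++k) if (!ringproc[k]) { start = k; break; }
      if (start == -1) {
        for (int k = 0; k < 8; ++k) group_of[k] = 0;
        ngroups = 1;
      } else {
        int g = -1;
        bool inrun = false;
        for (int s = 0; s < 8; ++s) {
          const int k = (start + s) % 8;
          if (ringproc[k]) {
            if (!inrun) { ++g; inrun = true; }
            group_of[k] = g;
          } else {
            inrun = false;
          }
        }
        ngroups = g + 1;
      }
    }
    std::vector<int> g_entry(ngroups, -1), g_root(ngroups, -1);
    for (int k = 0; k < 8; ++k) {
      if (!ringproc[k]) continue;
      const int g = group_of[k];
      if (g_entry[g] == -1 || rank[ringpix[k]] < rank[g_entry[g]])
        g_entry[g] = ringpix[k];
    }
    for (int g = 0; g < ngroups; ++g) g_root[g] = uf_find(par, g_entry[g]);

    // loop saddles: two ring groups already in the same component; only
    // saddles above loop_min are significant (basin-filling in background
    // noise produces countless irrelevant ones)
    for (int g1 = 0; v[p] >= loop_min && g1 < ngroups; ++g1) {
      for (int g2 = g1 + 1; g2 < ngroups; ++g2) {
        if (g_root[g1] == g_root[g2]) {
          ev_saddle.push_back(p);
          ev_entryA.push_back(g_entry[g1]);
          ev_entryB.push_back(g_entry[g2]);
          ev_loop.push_back(1);
        }
      }
    }

    // join p, then merge remaining distinct components through saddle p
    const int rootA0 = uf_find(par, attach);
    par[p] = rootA0;

    for (int g = 0; g < ngroups; ++g) {
      int rcur = uf_find(par, p);
      int rg = uf_find(par, g_entry[g]);
      if (rg == rcur) continue;
      const int peak_cur = peak[rcur], peak_g = peak[rg];
      // the younger peak (later in order = lower value) dies here
      const int young = (rank[peak_cur] > rank[peak_g]) ? peak_cur : peak_g;
      const int elder = (young == peak_cur) ? peak_g : peak_cur;
      pers[young] = v[young] - v[p];
      ev_saddle.push_back(p);
      ev_entryA.push_back(attach);
      ev_entryB.push_back(g_entry[g]);
      ev_loop.push_back(0);
      // union (keep rcur as root)
      par[rg] = rcur;
      peak[rcur] = elder;
    }
  }

  // surviving roots: infinite persistence
  for (long i = 0; i < N; ++i) {
    if (is_peak[i] && pers[i] < 0) {
      const int r = uf_find(par, (int)i);
      if (peak[r] == (int)i) pers[i] = R_PosInf;
    }
  }

  // steepest-ascent tracer
  auto ascend = [&](int q) {
    std::vector<int> path;
    path.push_back(q);
    int cur = q;
    for (;;) {
      const int cr = cur % nr, cc = cur / nr;
      int best = cur;
      for (int k = 0; k < 8; ++k) {
        const int rr = cr + ring_dr[k], c2 = cc + ring_dc[k];
        if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
        const int q2 = rr + c2 * nr;
        if (rank[q2] < rank[best]) best = q2;
      }
      if (best == cur) break;
      cur = best;
      path.push_back(cur);
    }
    return path;
  };

  const int nev = (int)ev_saddle.size();
  List arcs(nev);
  IntegerMatrix events(nev, 3);
  LogicalVector loopflag(nev);
  for (int e = 0; e < nev; ++e) {
    std::vector<int> pa = ascend(ev_entryA[e]);
    std::vector<int> pb = ascend(ev_entryB[e]);
    std::vector<int> full;
    full.reserve(pa.size() + pb.size() + 1);
    for (int i = (int)pa.size() - 1; i >= 0; --i) full.push_back(pa[i]);
    full.push_back(ev_saddle[e]);
    for (size_t i = 0; i < pb.size(); ++i) full.push_back(pb[i]);
    IntegerVector fv(full.size());
    for (size_t i = 0; i < full.size(); ++i) fv[i] = full[i] + 1; // 1-based
    arcs[e] = fv;
    events(e, 0) = ev_saddle[e] + 1;
    events(e, 1) = pa.back() + 1;  // terminal maximum on side A
    events(e, 2) = pb.back() + 1;  // terminal maximum on side B
    loopflag[e] = ev_loop[e] == 1;
  }

  std::vector<int> pk;
  std::vector<double> pk_pers;
  for (long i = 0; i < N; ++i) {
    if (is_peak[i]) {
      pk.push_back((int)i + 1);
      pk_pers.push_back(pers[i]);
    }
  }

  return List::create(
    _["peaks"] = wrap(pk),
    _["peak_persistence"] = wrap(pk_pers),
    _["events"] = events,
    _["is_loop"] = loopflag,
    _["arcs"] = arcs);
}

// Seeded region growing with a positive-gradient rule: an unvisited
// 8-neighbour q of a region pixel p joins the region when
// img[q] >= img[p] - tol. Implemented with an explicit queue so recursion
// depth is bounded.
// [[Rcpp::export(name = ".region_grow")]]
LogicalMatrix region_grow(NumericMatrix img, LogicalMatrix seeds,
                          double tol) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  std::queue<int> q;
  for (int i = 0; i < nr * nc; ++i) {
    if (seeds[i]) {
      out[i] = true;
      q.push(i);
    }
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + dr[k], cc = pc + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int n = rr + cc * nr;
      if (!out[n] && img[n] >= img[p] - tol) {
        out[n] = true;
        q.push(n);
      }
    }
  }
  return out;
}
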