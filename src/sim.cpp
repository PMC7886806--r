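#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Behavioural states (framework 2)
static const int S_SEARCHING = 0;
static const int S_PRODUCING = 1;
static const int S_USING_OWN = 2;
static const int S_USING_OTHER = 3;

static inline int sample_int(int n) {
  // uniform draw from 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return (k >= n) ? (n - 1) : k;
}

// constant-time membership set with uniform sampling (swap-pop + index)
struct NodeSet {
  std::vector<int> items;
  std::vector<int> pos;
  void init(int n) { pos.assign(n, -1); items.clear(); }
  inline void add(int i) {
    if (pos[i] < 0) { pos[i] = (int)items.size(); items.push_back(i); }
  }
  inline void remove(int i) {
    int p = pos[i];
    if (p >= 0) {
      int last = items.back();
      items[p] = last;
      pos[last] = p;
      items.pop_back();
      pos[i] = -1;
    }
  }
  inline int size() const { return (int)items.size(); }
};

// Single-run simulation engine shared by both frameworks.
//
// Types are 0 = A, 1 = B. ep[i] > 0 means node i holds an extended
// phenotype with that many cycles remaining; timers are decremented once at
// the end of every cycle and carry over unchanged when a token is reused.
//
// Recipient bookkeeping: `eligible[t]` holds the nodes of type t that could
// accept an abandoned token (framework 1: token-less; framework 2:
// token-less searchers), so the graph-wide fallback draw is O(1) instead of
// a full scan. `holders` tracks token owners for the timer sweep.
//
// uniform_parent: parent chosen ignoring fitness (validation mutant).
// base_fitness: per-type baseline (classical Moran special case; 1,1 in the
// standard model). log_eps: record per-token creation/removal cycles.
// [[Rcpp::export]]
List sim_run_cpp(const IntegerVector adj_ptr, const IntegerVector adj_idx,
                 const IntegerVector type_in, const IntegerVector ep_time_in,
                 const IntegerVector state_in, const IntegerVector residence_in,
                 const int framework, const int events_per_cycle,
                 const int cycle_limit, const bool stop_on_fixation,
                 const NumericVector alpha, const NumericVector beta,
                 const NumericVector gam, const LogicalVector produces,
                 const double birth_ep_chance, const int ep_lifetime,
                 const int state_time, const NumericVector base_fitness,
                 const bool uniform_parent, const bool log_eps) {
  RNGScope scope;
  IntegerVector type_v = clone(type_in), ep_v = clone(ep_time_in);
  IntegerVector state_v = clone(state_in), residence_v = clone(residence_in);
  const int n = type_v.size();
  int *type = INTEGER(type_v), *ep = INTEGER(ep_v);
  int *state = INTEGER(state_v), *residence = INTEGER(residence_v);
  const int *aptr = INTEGER(adj_ptr), *aidx = INTEGER(adj_idx);
  const double alph[2] = {alpha[0], alpha[1]};
  const double bet[2] = {beta[0], beta[1]};
  const double gm[2] = {gam[0], gam[1]};
  const double basef[2] = {base_fitness[0], base_fitness[1]};
  const bool prod[2] = {produces[0] != 0, produces[1] != 0};
  const bool reuse[2] = {gm[0] != -1.0, gm[1] != -1.0};

  int max_deg = 0;
  for (int i = 0; i < n; ++i) {
    int d = aptr[i + 1] - aptr[i];
    if (d > max_deg) max_deg = d;
  }
  std::vector<double> wbuf(max_deg);
  std::vector<int> cand(max_deg);

  NodeSet eligible[2], holders;
  eligible[0].init(n); eligible[1].init(n); holders.init(n);
  for (int i = 0; i < n; ++i) {
    if (ep[i] > 0) holders.add(i);
    bool el = (ep[i] == 0) && (framework == 1 || state[i] == S_SEARCHING);
    if (el) eligible[type[i]].add(i);
  }
  // refresh node i's recipient eligibility after any type/state/token change
  auto refresh = [&](int i) {
    eligible[0].remove(i);
    eligible[1].remove(i);
    if (ep[i] == 0 && (framework == 1 || state[i] == S_SEARCHING))
      eligible[type[i]].add(i);
  };

  // token event log
  std::vector<int> ep_owner_id(log_eps ? n : 0, -1);
  std::vector<int> log_created, log_removed, log_reason; // 1=expired 2=destroyed
  auto log_new = [&](int i, int cyc) {
    if (log_eps) {
      ep_owner_id[i] = (int)log_created.size();
      log_created.push_back(cyc);
      log_removed.push_back(-1);
      log_reason.push_back(0);
    }
  };
  auto log_gone = [&](int i, int cyc, int reason) {
    if (log_eps) {
      log_removed[ep_owner_id[i]] = cyc;
      log_reason[ep_owner_id[i]] = reason;
      ep_owner_id[i] = -1;
    }
  };
  if (log_eps) {
    for (int i = 0; i < n; ++i) if (ep[i] > 0) log_new(i, 0);
  }

  int count_a = 0;
  for (int i = 0; i < n; ++i) if (type[i] == 0) ++count_a;

  int cycle = 0;
  bool fixed = stop_on_fixation && (count_a == 0 || count_a == n);

  while (!fixed && cycle < cycle_limit) {
    ++cycle;

    for (int e = 0; e < events_per_cycle; ++e) {
      const int dying = sample_int(n);
      const int a0 = aptr[dying], a1 = aptr[dying + 1];
      const int deg = a1 - a0;

      // parent: neighbour of the dying node, weighted by relative fitness
      int parent;
      if (uniform_parent) {
        parent = aidx[a0 + sample_int(deg)];
      } else {
        double tot = 0.0;
        for (int k = 0; k < deg; ++k) {
          const int j = aidx[a0 + k];
          const int t = type[j];
          double w;
          if (framework == 1) {
            w = basef[t] + (ep[j] > 0 ? alph[t] : 0.0);
          } else {
            switch (state[j]) {
              case S_PRODUCING:   w = basef[t] - bet[t]; break;
              case S_USING_OWN:   w = basef[t] + alph[t]; break;
              case S_USING_OTHER: w = basef[t] + gm[t]; break;
              default:            w = basef[t];
            }
          }
          wbuf[k] = w;
          tot += w;
        }
        parent = aidx[a1 - 1];
        double u = unif_rand() * tot, acc = 0.0;
        for (int k = 0; k < deg; ++k) {
          acc += wbuf[k];
          if (u < acc) { parent = aidx[a0 + k]; break; }
        }
      }
      const int ptype = type[parent];

      // offer the dying node's token before the newborn is placed.
      // framework 1: conspecific reuse only -- a token-less node of the
      // dying node's own (reuse-capable) type, neighbours first, then
      // anywhere in the graph. framework 2: any token-less searcher of a
      // reuse-capable type, same neighbour-first order, and the recipient
      // flips to USING_OTHER. otherwise the token vanishes. the timer
      // carries over unchanged.
      if (ep[dying] > 0) {
        const int dtype = type[dying];
        int recip = -1;
        if (framework == 1 ? reuse[dtype] : (reuse[0] || reuse[1])) {
          int cnt = 0;
          for (int k = a0; k < a1; ++k) {
            const int j = aidx[k];
            if (ep[j] != 0) continue;
            if (framework == 1) {
              if (type[j] == dtype) cand[cnt++] = j;
            } else {
              if (state[j] == S_SEARCHING && reuse[type[j]]) cand[cnt++] = j;
            }
          }
          if (cnt > 0) {
            recip = cand[sample_int(cnt)];
          } else if (framework == 1) {
            if (eligible[dtype].size() > 0)
              recip = eligible[dtype].items[sample_int(eligible[dtype].size())];
          } else {
            const int na = reuse[0] ? eligible[0].size() : 0;
            const int nb = reuse[1] ? eligible[1].size() : 0;
            if (na + nb > 0) {
              int k = sample_int(na + nb);
              recip = (k < na) ? eligible[0].items[k]
                               : eligible[1].items[k - na];
            }
          }
        }
        if (recip >= 0) {
          ep[recip] = ep[dying];
          holders.add(recip);
          if (log_eps) ep_owner_id[recip] = ep_owner_id[dying];
          if (framework == 2) {
            state[recip] = S_USING_OTHER;
            residence[recip] = 0;
          }
          refresh(recip);
        } else {
          log_gone(dying, cycle, 2);
        }
        ep[dying] = 0;
        holders.remove(dying);
      }

      // newborn replaces the dying node
      if (type[dying] == 0) --count_a;
      if (ptype == 0) ++count_a;
      type[dying] = ptype;
      if (framework == 1) {
        if (prod[ptype] && birth_ep_chance > 0.0 &&
            unif_rand() < birth_ep_chance) {
          ep[dying] = ep_lifetime;
          holders.add(dying);
          log_new(dying, cycle);
        }
      } else {
        state[dying] = S_SEARCHING;
        residence[dying] = 0;
      }
      refresh(dying);
    }

    // end-of-cycle sweep: residence-driven transitions (framework 2), then
    // one timer decrement for every token
    if (framework == 2) {
      for (int i = 0; i < n; ++i) {
        ++residence[i];
        if (state[i] == S_SEARCHING) {
          if (bet[type[i]] != -1.0 && residence[i] >= state_time) {
            state[i] = S_PRODUCING;
            residence[i] = 0;
            refresh(i);
          }
        } else if (state[i] == S_PRODUCING && residence[i] >= state_time) {
          state[i] = S_USING_OWN;
          residence[i] = 0;
          ep[i] = ep_lifetime;
          holders.add(i);
          log_new(i, cycle);
        }
      }
    }
    for (int h = holders.size() - 1; h >= 0; --h) {
      const int i = holders.items[h];
      if (--ep[i] == 0) {
        holders.remove(i);
        log_gone(i, cycle, 1);
        if (framework == 2) {
          state[i] = S_SEARCHING;
          residence[i] = 0;
        }
        refresh(i);
      }
    }

    if ((cycle & 1023) == 0) Rcpp::checkUserInterrupt();
    if (stop_on_fixation && (count_a == 0 || count_a == n)) fixed = true;
  }

  int ep_total = 0, ep_a = 0, ep_b = 0;
  IntegerVector state_counts(4);
  for (int i = 0; i < n; ++i) {
    if (ep[i] > 0) {
      ++ep_total;
      if (type[i] == 0) ++ep_a; else ++ep_b;
    }
    ++state_counts[state[i]];
  }

  List out = List::create(
    _["count_a"] = count_a,
    _["count_b"] = n - count_a,
    _["cycles"] = cycle,
    _["ep_count"] = ep_total,
    _["ep_count_a"] = ep_a,
    _["ep_count_b"] = ep_b,
    _["state_counts"] = state_counts,
    _["type"] = type_v,
    _["ep_time"] = ep_v,
    _["state"] = state_v,
    _["residence"] = residence_v
  );
  if (log_eps) {
    out["ep_log"] = List::create(
      _["created"] = wrap(log_created),
      _["removed"] = wrap(log_removed),
      _["reason"] = wrap(log_reason));
  }
  return out;
}
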