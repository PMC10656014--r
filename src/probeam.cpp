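// Core decoder routines: peptide-database index, factored state transitions
// (detachment -> dye loss -> Edman degradation), greedy initial-state search,
// and the beam recursion.  All probability accumulation across cycles is in
// log space; within-step transition products are safe in linear space.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <deque>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double e, l, m, p_d, mu, sigma, sigma_b, h;
  int nd, nc;
  double nb; // beam width; double so Inf is representable
};

Params parse_params(const List& p) {
  Params q;
  q.e = as<double>(p["e"]);
  q.l = as<double>(p["l"]);
  q.m = as<double>(p["m"]);
  q.p_d = as<double>(p["p_d"]);
  q.mu = as<double>(p["mu"]);
  q.sigma = as<double>(p["sigma"]);
  q.sigma_b = as<double>(p["sigma_b"]);
  q.h = as<double>(p["h"]);
  q.nd = as<int>(p["n_colors"]);
  q.nc = as<int>(p["n_cycles"]);
  q.nb = as<double>(p["n_beam"]);
  return q;
}

struct PBState {
  std::vector<int> N, K;
  std::string R;
};

void append_counts(std::string& k, const std::vector<int>& v) {
  for (size_t i = 0; i < v.size(); ++i) {
    if (i) k += ',';
    k += std::to_string(v[i]);
  }
}

// canonical key "R|n1,n2,...|k1,k2,..."; must stay in sync with state_key() in R
std::string state_key(const PBState& s) {
  std::string k = s.R;
  k += '|';
  append_counts(k, s.N);
  k += '|';
  append_counts(k, s.K);
  return k;
}

std::string eta_key(const std::string& R, const std::vector<int>& N) {
  std::string k = R;
  k += '|';
  append_counts(k, N);
  return k;
}

struct PBDB {
  int nd;
  int n_pep;
  std::vector<std::string> dseq;               // unique dye sequences
  std::vector<double> pD;                      // prior per dye sequence
  std::vector<std::vector<int>> pep_ids;       // 1-based peptide ids per dye sequence
  std::vector<std::vector<double>> pep_w;      // P_P of those peptides
  // prefix index: (removed prefix R, remaining counts N) -> dye-sequence indices
  std::unordered_map<std::string, std::vector<int>> idx;
};

std::vector<int> count_colors(const std::string& d, size_t from, int nd) {
  std::vector<int> c(nd, 0);
  for (size_t j = from; j < d.size(); ++j)
    if (d[j] != '.') c[d[j] - '0']++;
  return c;
}

PBState state_from_list(const List& s) {
  PBState st;
  IntegerVector N = s["N"], K = s["K"];
  st.N.assign(N.begin(), N.end());
  st.K.assign(K.begin(), K.end());
  st.R = as<std::string>(s["R"]);
  return st;
}

List state_to_list(const PBState& s) {
  List out = List::create(_["N"] = IntegerVector(s.N.begin(), s.N.end()),
                          _["K"] = IntegerVector(s.K.begin(), s.K.end()),
                          _["R"] = s.R);
  out.attr("class") = "pb_state";
  return out;
}

bool all_zero(const std::vector<int>& v) {
  for (int x : v) if (x != 0) return false;
  return true;
}

double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

double sigma_eff(int k, const Params& p) {
  return std::sqrt(k * p.sigma * p.sigma + p.sigma_b * p.sigma_b);
}

double obs_loglik(const double* x, const std::vector<int>& K, const Params& p) {
  double s = 0.0;
  for (int i = 0; i < p.nd; ++i)
    s += R::dnorm4(x[i], K[i] * p.mu, sigma_eff(K[i], p), 1);
  return s;
}

// h-threshold test on an attached-count vector; boundary inclusive
bool prune_ok(const double* x, const std::vector<int>& K, const Params& p) {
  if (!std::isfinite(p.h)) return true;
  for (int i = 0; i < p.nd; ++i)
    if (std::fabs(x[i] - K[i] * p.mu) / sigma_eff(K[i], p) > p.h) return false;
  return true;
}

// per-color density in K, log scale
double color_logdens(double x, int k, const Params& p) {
  return R::dnorm4(x, k * p.mu, sigma_eff(k, p), 1);
}

// integer argmax of the per-color density over [0, nbound]; local search from
// round(x/mu) is exact because the density is unimodal in K; ties go low
int kopt_color(double x, int nbound, const Params& p) {
  int k = (int) std::lround(x / p.mu);
  if (k < 0) k = 0;
  if (k > nbound) k = nbound;
  while (k > 0 && color_logdens(x, k - 1, p) >= color_logdens(x, k, p)) --k;
  while (k < nbound && color_logdens(x, k + 1, p) > color_logdens(x, k, p)) ++k;
  return k;
}

// P_DyeMiss-style binomial thinning product: prob of keeping K out of N with
// per-unit retention 1-rate
double thin_prob(const std::vector<int>& K, const std::vector<int>& N, double rate) {
  double p = 1.0;
  for (size_t i = 0; i < K.size(); ++i)
    p *= R::dbinom((double) K[i], (double) N[i], 1.0 - rate, 0);
  return p;
}

const std::vector<int>* eta_lookup(const PBDB& db, const std::vector<int>& N,
                                   const std::string& R) {
  auto it = db.idx.find(eta_key(R, N));
  if (it == db.idx.end()) return nullptr;
  return &(it->second);
}

// marginal removal probabilities over the next symbol, given (N, R):
// out[0] = '.', out[1+i] = color i.  Returns false when eta is empty.
bool removal_probs(const PBDB& db, const std::vector<int>& N, const std::string& R,
                   std::vector<double>& out) {
  const std::vector<int>* mem = eta_lookup(db, N, R);
  if (!mem || mem->empty()) return false;
  out.assign(db.nd + 1, 0.0);
  double W = 0.0;
  for (int di : *mem) {
    const std::string& d = db.dseq[di];
    W += db.pD[di];
    char c = (R.size() < d.size()) ? d[R.size()] : '.';
    int slot = (c == '.') ? 0 : (c - '0') + 1;
    out[slot] += db.pD[di];
  }
  for (double& v : out) v /= W;
  return true;
}

// weighted successor set with deterministic (insertion) order and merging
struct SuccSet {
  std::vector<PBState> st;
  std::vector<double> p;
  std::vector<std::string> key;
  std::unordered_map<std::string, size_t> pos;

  void add(const PBState& s, double prob) {
    std::string k = state_key(s);
    auto it = pos.find(k);
    if (it == pos.end()) {
      pos.emplace(k, st.size());
      st.push_back(s);
      p.push_back(prob);
      key.push_back(k);
    } else {
      p[it->second] += prob;
    }
  }
};

// enumerate dye-loss successors of s (K' <= K) into out with probabilities;
// when x != nullptr, successors failing the h test are dropped (mass discarded)
void dye_loss_succ(const PBState& s, const double* x, const Params& par,
                   SuccSet& out, bool* pruned) {
  if (all_zero(s.K)) { out.add(s, 1.0); return; }
  std::vector<int> kp(s.K.size(), 0);
  for (;;) {
    double p = thin_prob(kp, s.K, par.l);
    PBState nxt = s;
    nxt.K = kp;
    if (x == nullptr || prune_ok(x, kp, par)) {
      out.add(nxt, p);
    } else if (pruned) {
      *pruned = true;
    }
    // odometer over 0..K_i
    size_t i = 0;
    while (i < kp.size() && kp[i] == s.K[i]) { kp[i] = 0; ++i; }
    if (i == kp.size()) break;
    kp[i]++;
  }
}

// Edman-degradation successors of s, scaled by base mass
bool edman_succ(const PBDB& db, const PBState& s, const Params& par,
                double base, SuccSet& out) {
  if (all_zero(s.K)) { out.add(s, base); return true; }
  std::vector<double> prem;
  if (!removal_probs(db, s.N, s.R, prem)) return false;
  out.add(s, base * par.e); // Edman failure
  double succp = base * (1.0 - par.e);
  if (prem[0] > 0) { // unlabeled residue removed
    PBState nxt = s;
    nxt.R += '.';
    out.add(nxt, succp * prem[0]);
  }
  for (int i = 0; i < db.nd; ++i) {
    if (prem[i + 1] <= 0) continue;
    double pa = (double) s.K[i] / (double) s.N[i];
    PBState rem = s;
    rem.R += (char) ('0' + i);
    rem.N[i] -= 1;
    if (pa > 0) { // fluorophore was attached to the removed residue
      PBState la = rem;
      la.K[i] -= 1;
      out.add(la, succp * prem[i + 1] * pa);
    }
    if (pa < 1) { // labeled residue removed but its fluorophore was absent
      out.add(rem, succp * prem[i + 1] * (1.0 - pa));
    }
  }
  return true;
}

// full one-cycle composition: detachment -> dye loss -> Edman.  When an
// observation is supplied, composed successors whose attached counts fail
// the h test against it are dropped (mass discarded): the pruning acts on
// the states that are about to be scored with x_t, so a successful Edman
// removal never prunes the surviving path.
bool one_cycle(const PBDB& db, const PBState& s, const double* x,
               const Params& par, SuccSet& out, bool* pruned) {
  SuccSet tmp;
  SuccSet& tgt = (x == nullptr) ? out : tmp;
  if (all_zero(s.K)) {
    tgt.add(s, 1.0);
  } else {
    // detach branch: absorbing through dye loss and Edman
    PBState det = s;
    std::fill(det.K.begin(), det.K.end(), 0);
    tgt.add(det, par.p_d);
    double surv = 1.0 - par.p_d;
    if (surv > 0) {
      // dye-loss lattice under the surviving branch
      std::vector<int> kp(s.K.size(), 0);
      for (;;) {
        double pl = thin_prob(kp, s.K, par.l);
        PBState s1 = s;
        s1.K = kp;
        if (!edman_succ(db, s1, par, surv * pl, tgt)) return false;
        size_t i = 0;
        while (i < kp.size() && kp[i] == s.K[i]) { kp[i] = 0; ++i; }
        if (i == kp.size()) break;
        kp[i]++;
      }
    }
  }
  if (x != nullptr) {
    for (size_t j = 0; j < tmp.st.size(); ++j) {
      if (prune_ok(x, tmp.st[j].K, par)) out.add(tmp.st[j], tmp.p[j]);
      else if (pruned) *pruned = true;
    }
  }
  return true;
}

struct Beam {
  std::vector<PBState> st;
  std::vector<double> logw; // normalized: logsumexp == 0
};

List beam_to_list(const Beam& b, bool pruned, bool empty) {
  List states(b.st.size());
  for (size_t i = 0; i < b.st.size(); ++i) states[i] = state_to_list(b.st[i]);
  return List::create(_["states"] = states,
                      _["logw"] = NumericVector(b.logw.begin(), b.logw.end()),
                      _["pruned"] = pruned,
                      _["empty"] = empty);
}

void normalize_truncate(std::vector<PBState>& st, std::vector<double>& lw,
                        const std::vector<std::string>& keys, double nb,
                        Beam& out) {
  std::vector<size_t> ord(st.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (lw[a] != lw[b]) return lw[a] > lw[b];
    return keys[a] < keys[b];
  });
  size_t keep = ord.size();
  if (std::isfinite(nb) && (double) keep > nb) keep = (size_t) nb;
  out.st.clear();
  out.logw.clear();
  double z = R_NegInf;
  for (size_t i = 0; i < keep; ++i) z = logaddexp(z, lw[ord[i]]);
  for (size_t i = 0; i < keep; ++i) {
    out.st.push_back(st[ord[i]]);
    out.logw.push_back(lw[ord[i]] - z);
  }
}

// one beam recursion step; returns false when every successor was pruned away
bool beam_step_core(const PBDB& db, const Beam& b, const double* x,
                    const Params& par, Beam& out, bool* pruned) {
  std::unordered_map<std::string, size_t> pos;
  std::vector<PBState> st;
  std::vector<double> lw;
  std::vector<std::string> keys;
  for (size_t i = 0; i < b.st.size(); ++i) {
    SuccSet succ;
    if (!one_cycle(db, b.st[i], x, par, succ, pruned))
      stop("state inconsistent with the database (empty eta)");
    for (size_t j = 0; j < succ.st.size(); ++j) {
      if (succ.p[j] <= 0) continue;
      double contrib = b.logw[i] + std::log(succ.p[j]);
      auto it = pos.find(succ.key[j]);
      if (it == pos.end()) {
        pos.emplace(succ.key[j], st.size());
        st.push_back(succ.st[j]);
        lw.push_back(contrib);
        keys.push_back(succ.key[j]);
      } else {
        lw[it->second] = logaddexp(lw[it->second], contrib);
      }
    }
  }
  if (st.empty()) return false;
  for (size_t i = 0; i < st.size(); ++i) lw[i] += obs_loglik(x, st[i].K, par);
  normalize_truncate(st, lw, keys, par.nb, out);
  return true;
}

// ---- greedy initial-state search ----

struct IdealState {
  std::vector<int> N;
  double logp; // log P(S_0^I.N = N)
};

std::vector<IdealState> ideal_states_core(const PBDB& db) {
  std::vector<IdealState> out;
  std::unordered_map<std::string, size_t> pos;
  for (size_t j = 0; j < db.dseq.size(); ++j) {
    std::vector<int> c = count_colors(db.dseq[j], 0, db.nd);
    std::string k;
    append_counts(k, c);
    auto it = pos.find(k);
    if (it == pos.end()) {
      pos.emplace(k, out.size());
      IdealState s;
      s.N = c;
      s.logp = db.pD[j];
      out.push_back(s);
    } else {
      out[it->second].logp += db.pD[j];
    }
  }
  for (auto& s : out) s.logp = std::log(s.logp);
  return out;
}

struct Cand {
  PBState s;
  double logp;
  std::string key;
};

// exact top-N_B initial states by P_alpha; the P_u bound only skips nodes that
// are provably dominated (observation density is unimodal per color)
void greedy_initial_core(const PBDB& db, const double* x0, const Params& par,
                         std::vector<Cand>& list) {
  std::vector<IdealState> ideal = ideal_states_core(db);
  // order ideal states by || x0/mu - N ||, ties by canonical N key
  std::vector<size_t> ord(ideal.size());
  std::vector<double> dist(ideal.size());
  std::vector<std::string> nkey(ideal.size());
  for (size_t j = 0; j < ideal.size(); ++j) {
    ord[j] = j;
    double d2 = 0;
    for (int i = 0; i < db.nd; ++i) {
      double dd = x0[i] / par.mu - ideal[j].N[i];
      d2 += dd * dd;
    }
    dist[j] = d2;
    append_counts(nkey[j], ideal[j].N);
  }
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (dist[a] != dist[b]) return dist[a] < dist[b];
    return nkey[a] < nkey[b];
  });

  list.clear();
  std::unordered_set<std::string> inlist;
  auto better = [](double lp1, const std::string& k1, double lp2,
                   const std::string& k2) {
    if (lp1 != lp2) return lp1 > lp2;
    return k1 < k2;
  };
  bool nb_finite = std::isfinite(par.nb);
  size_t nb = nb_finite ? (size_t) par.nb : (size_t) -1;
  auto worst_index = [&]() {
    size_t w = 0;
    for (size_t i = 1; i < list.size(); ++i)
      if (better(list[w].logp, list[w].key, list[i].logp, list[i].key)) w = i;
    return w;
  };
  // same summation order as the search loop below so values are bit-identical
  auto palpha_of = [&](const IdealState& is, const std::vector<int>& K) {
    return (is.logp + obs_loglik(x0, K, par)) + std::log(thin_prob(K, is.N, par.m));
  };
  auto try_insert = [&](const IdealState& is, const std::vector<int>& K,
                        double logpa) {
    PBState s;
    s.N = is.N;
    s.K = K;
    std::string k = state_key(s);
    if (inlist.count(k)) return;
    if (list.size() < nb) {
      list.push_back(Cand{s, logpa, k});
      inlist.insert(k);
    } else {
      size_t w = worst_index();
      if (better(logpa, k, list[w].logp, list[w].key)) {
        inlist.erase(list[w].key);
        list[w] = Cand{s, logpa, k};
        inlist.insert(k);
      }
    }
  };

  // seed with the N_B nearest ideal states at their bounded optimal K
  std::vector<std::vector<int>> kopt(ideal.size());
  for (size_t j = 0; j < ideal.size(); ++j) {
    kopt[j].resize(db.nd);
    for (int i = 0; i < db.nd; ++i)
      kopt[j][i] = kopt_color(x0[i], ideal[j].N[i], par);
  }
  for (size_t r = 0; r < ord.size() && r < nb; ++r) {
    size_t j = ord[r];
    try_insert(ideal[j], kopt[j], palpha_of(ideal[j], kopt[j]));
  }

  // breadth-first search over the deviation lattice of each ideal state
  for (size_t r = 0; r < ord.size(); ++r) {
    size_t j = ord[r];
    const IdealState& is = ideal[j];
    std::deque<std::vector<int>> q;
    std::unordered_set<std::string> visited;
    q.push_back(kopt[j]);
    {
      std::string k0;
      append_counts(k0, kopt[j]);
      visited.insert(k0);
    }
    while (!q.empty()) {
      std::vector<int> K = q.front();
      q.pop_front();
      double logpu = is.logp + obs_loglik(x0, K, par);
      if (list.size() >= nb) {
        size_t w = worst_index();
        if (logpu < list[w].logp) continue; // bound: subtree dominated
      }
      try_insert(is, K, logpu + std::log(thin_prob(K, is.N, par.m)));
      for (int i = 0; i < db.nd; ++i) {
        for (int dir = -1; dir <= 1; dir += 2) {
          int v = K[i] + dir;
          if (v < 0 || v > is.N[i]) continue;
          if (std::abs(v - kopt[j][i]) <= std::abs(K[i] - kopt[j][i])) continue;
          std::vector<int> Kn = K;
          Kn[i] = v;
          std::string kk;
          append_counts(kk, Kn);
          if (visited.insert(kk).second) q.push_back(Kn);
        }
      }
    }
  }

  std::sort(list.begin(), list.end(), [&](const Cand& a, const Cand& b) {
    if (a.logp != b.logp) return a.logp > b.logp;
    return a.key < b.key;
  });
}

void initial_beam_core(const PBDB& db, const double* x0, const Params& par,
                       Beam& out, std::vector<double>* palpha) {
  std::vector<Cand> list;
  greedy_initial_core(db, x0, par, list);
  double z = R_NegInf;
  for (auto& c : list) z = logaddexp(z, c.logp);
  out.st.clear();
  out.logw.clear();
  for (auto& c : list) {
    out.st.push_back(c.s);
    out.logw.push_back(c.logp - z);
    if (palpha) palpha->push_back(c.logp);
  }
}

// ---- decoding ----

struct DecodeOut {
  std::vector<double> post;
  bool pruned = false;
  bool undecodable = false;
};

void peptide_posterior(const PBDB& db, const Beam& b, std::vector<double>& post) {
  post.assign(db.n_pep, 0.0);
  for (size_t i = 0; i < b.st.size(); ++i) {
    const std::vector<int>* mem = eta_lookup(db, b.st[i].N, b.st[i].R);
    if (!mem) continue;
    double W = 0.0;
    for (int di : *mem) W += db.pD[di];
    double w = std::exp(b.logw[i]);
    for (int di : *mem) {
      const std::vector<int>& ids = db.pep_ids[di];
      const std::vector<double>& ws = db.pep_w[di];
      for (size_t u = 0; u < ids.size(); ++u)
        post[ids[u] - 1] += w * ws[u] / W;
    }
  }
  double tot = 0.0;
  for (double v : post) tot += v;
  if (tot > 0) for (double& v : post) v /= tot;
}

void decode_core(const PBDB& db, const std::vector<std::vector<double>>& x,
                 const Params& par, DecodeOut& out) {
  Beam beam;
  initial_beam_core(db, x[0].data(), par, beam, nullptr);
  for (int t = 1; t < (int) x.size(); ++t) {
    Beam nxt;
    if (!beam_step_core(db, beam, x[t].data(), par, nxt, &out.pruned)) {
      out.undecodable = true;
      out.post.assign(db.n_pep, NA_REAL);
      return;
    }
    beam = nxt;
  }
  peptide_posterior(db, beam, out.post);
}

PBDB* get_db(SEXP ptr) {
  Rcpp::XPtr<PBDB> p(ptr);
  return p.get();
}

} // namespace

// [[Rcpp::export]]
bool pb_ptr_ok(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export]]
SEXP pb_db_build(CharacterVector dseqs, NumericVector pD, List pep_ids,
                 List pep_w, int n_colors) {
  PBDB* db = new PBDB();
  db->nd = n_colors;
  int npep = 0;
  for (int j = 0; j < dseqs.size(); ++j) {
    std::string d = as<std::string>(dseqs[j]);
    db->dseq.push_back(d);
    db->pD.push_back(pD[j]);
    IntegerVector ids = pep_ids[j];
    NumericVector ws = pep_w[j];
    db->pep_ids.emplace_back(ids.begin(), ids.end());
    db->pep_w.emplace_back(ws.begin(), ws.end());
    for (int id : ids) npep = std::max(npep, id);
    for (size_t cut = 0; cut <= d.size(); ++cut) {
      std::vector<int> c = count_colors(d, cut, n_colors);
      db->idx[eta_key(d.substr(0, cut), c)].push_back(j);
    }
  }
  db->n_pep = npep;
  Rcpp::XPtr<PBDB> ptr(db, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector pb_eta(SEXP dbptr, IntegerVector N, std::string R) {
  PBDB* db = get_db(dbptr);
  std::vector<int> n(N.begin(), N.end());
  const std::vector<int>* mem = eta_lookup(*db, n, R);
  if (!mem) return IntegerVector(0);
  IntegerVector out(mem->size());
  for (size_t i = 0; i < mem->size(); ++i) out[i] = (*mem)[i] + 1;
  return out;
}

// [[Rcpp::export]]
NumericVector pb_removal_probs(SEXP dbptr, IntegerVector N, std::string R) {
  PBDB* db = get_db(dbptr);
  std::vector<int> n(N.begin(), N.end());
  std::vector<double> out;
  if (!removal_probs(*db, n, R, out))
    stop("inconsistent state: no dye sequence matches (N, R)");
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double pb_obs_logprob(NumericVector x, IntegerVector K, List params) {
  Params par = parse_params(params);
  std::vector<int> k(K.begin(), K.end());
  return obs_loglik(REAL(x), k, par);
}

// [[Rcpp::export]]
IntegerVector pb_kopt(NumericVector x, IntegerVector n_bound, List params) {
  Params par = parse_params(params);
  IntegerVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = kopt_color(x[i], n_bound[i], par);
  return out;
}

// [[Rcpp::export]]
bool pb_prune_pass(NumericVector x, IntegerVector K, List params) {
  Params par = parse_params(params);
  std::vector<int> k(K.begin(), K.end());
  return prune_ok(REAL(x), k, par);
}

static List succ_to_list(const SuccSet& succ) {
  List states(succ.st.size());
  for (size_t i = 0; i < succ.st.size(); ++i) states[i] = state_to_list(succ.st[i]);
  return List::create(_["states"] = states,
                      _["prob"] = NumericVector(succ.p.begin(), succ.p.end()));
}

// [[Rcpp::export]]
List pb_dye_loss_step(List state, Nullable<NumericVector> x, List params) {
  Params par = parse_params(params);
  PBState s = state_from_list(state);
  SuccSet succ;
  bool pruned = false;
  const double* xp = nullptr;
  NumericVector xv;
  if (x.isNotNull()) {
    xv = x.get();
    xp = REAL(xv);
  }
  dye_loss_succ(s, xp, par, succ, &pruned);
  List out = succ_to_list(succ);
  out["pruned"] = pruned;
  return out;
}

// [[Rcpp::export]]
List pb_edman_step(SEXP dbptr, List state, List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  PBState s = state_from_list(state);
  SuccSet succ;
  if (!edman_succ(*db, s, par, 1.0, succ))
    stop("inconsistent state: no dye sequence matches (N, R)");
  return succ_to_list(succ);
}

// [[Rcpp::export]]
List pb_one_cycle(SEXP dbptr, List state, Nullable<NumericVector> x, List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  PBState s = state_from_list(state);
  SuccSet succ;
  bool pruned = false;
  const double* xp = nullptr;
  NumericVector xv;
  if (x.isNotNull()) {
    xv = x.get();
    xp = REAL(xv);
  }
  if (!one_cycle(*db, s, xp, par, succ, &pruned))
    stop("inconsistent state: no dye sequence matches (N, R)");
  List out = succ_to_list(succ);
  out["pruned"] = pruned;
  return out;
}

// [[Rcpp::export]]
List pb_ideal_states(SEXP dbptr) {
  PBDB* db = get_db(dbptr);
  std::vector<IdealState> ideal = ideal_states_core(*db);
  List Ns(ideal.size());
  NumericVector lp(ideal.size());
  for (size_t j = 0; j < ideal.size(); ++j) {
    Ns[j] = IntegerVector(ideal[j].N.begin(), ideal[j].N.end());
    lp[j] = ideal[j].logp;
  }
  return List::create(_["N"] = Ns, _["logp"] = lp);
}

// [[Rcpp::export]]
List pb_greedy_initial(SEXP dbptr, NumericVector x0, List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  Beam beam;
  std::vector<double> palpha;
  initial_beam_core(*db, REAL(x0), par, beam, &palpha);
  List out = beam_to_list(beam, false, beam.st.empty());
  out["log_palpha"] = NumericVector(palpha.begin(), palpha.end());
  return out;
}

// [[Rcpp::export]]
List pb_beam_step(SEXP dbptr, List states, NumericVector logw, NumericVector x,
                  List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  Beam b;
  for (int i = 0; i < states.size(); ++i) {
    b.st.push_back(state_from_list(states[i]));
    b.logw.push_back(logw[i]);
  }
  Beam out;
  bool pruned = false;
  bool ok = beam_step_core(*db, b, REAL(x), par, out, &pruned);
  return beam_to_list(out, pruned, !ok);
}

// [[Rcpp::export]]
List pb_decode_read(SEXP dbptr, NumericMatrix X, List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  std::vector<std::vector<double>> x(X.ncol());
  for (int t = 0; t < X.ncol(); ++t)
    x[t].assign(X.column(t).begin(), X.column(t).end());
  DecodeOut out;
  decode_core(*db, x, par, out);
  return List::create(_["posterior"] = NumericVector(out.post.begin(), out.post.end()),
                      _["pruned"] = out.pruned,
                      _["undecodable"] = out.undecodable);
}

// [[Rcpp::export]]
List pb_decode_batch(SEXP dbptr, NumericVector arr, List params) {
  Params par = parse_params(params);
  PBDB* db = get_db(dbptr);
  IntegerVector dim = arr.attr("dim");
  int n = dim[0], nd = dim[1], nt = dim[2];
  if (nd != db->nd) stop("read color dimension does not match the database");
  NumericMatrix post(n, db->n_pep);
  LogicalVector pruned(n), undec(n);
  const double* a = REAL(arr);
  for (int r = 0; r < n; ++r) {
    std::vector<std::vector<double>> x(nt, std::vector<double>(nd));
    for (int t = 0; t < nt; ++t)
      for (int i = 0; i < nd; ++i)
        x[t][i] = a[r + (size_t) n * (i + (size_t) nd * t)];
    DecodeOut out;
    decode_core(*db, x, par, out);
    for (int pp = 0; pp < db->n_pep; ++pp) post(r, pp) = out.post[pp];
    pruned[r] = out.pruned;
    undec[r] = out.undecodable;
    if ((r + 1) % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["posterior"] = post, _["pruned"] = pruned,
                      _["undecodable"] = undec);
}
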