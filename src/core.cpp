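// Compiled core: 2-bit k-mer index, pseudoalignment to equivalence classes,
// uniform-start read simulation, and the EM abundance estimator. Kept in C++
// so that desk-scale simulations (millions of reads) stay interactive.
#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> tx_id;
  std::vector<int> tx_len;
  std::vector<int> tx_gene;              // 0-based gene index per transcript
  std::vector<std::string> gene_id;
  std::unordered_map<uint64_t, std::vector<int> > kmap; // kmer -> sorted tx idx (0-based)
  long long n_kmer_occ;                  // total indexed k-mer occurrences
  // EC registry: ids assigned in order of first observation within this index
  std::map<std::vector<int>, int> ec_of_set;
  std::vector<std::vector<int> > ec_sets;
};

// Enumerate valid k-mers of s with a rolling 2-bit encoding; calls f(key) per kmer.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t key = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(key);
  }
}

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector tx_seq, CharacterVector tx_id,
                     CharacterVector tx_gene_id, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  XPtr<KmerIndex> xp(new KmerIndex(), true);
  KmerIndex& idx = *xp;
  idx.k = k;
  idx.n_kmer_occ = 0;
  std::map<std::string, int> gene_idx;
  int n = tx_seq.size();
  for (int t = 0; t < n; ++t) {
    std::string gid = as<std::string>(tx_gene_id[t]);
    std::map<std::string, int>::iterator it = gene_idx.find(gid);
    int gi;
    if (it == gene_idx.end()) {
      gi = (int)idx.gene_id.size();
      gene_idx[gid] = gi;
      idx.gene_id.push_back(gid);
    } else gi = it->second;
    std::string s = as<std::string>(tx_seq[t]);
    idx.tx_id.push_back(as<std::string>(tx_id[t]));
    idx.tx_len.push_back((int)s.size());
    idx.tx_gene.push_back(gi);
    for_each_kmer(s, k, [&](uint64_t key) {
      idx.n_kmer_occ++;
      std::vector<int>& v = idx.kmap[key];
      if (v.empty() || v.back() != t) v.push_back(t);
    });
  }
  return xp;
}

// [[Rcpp::export(name = ".index_stats_cpp")]]
List index_stats_cpp(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return List::create(_["k"] = xp->k,
                      _["n_transcripts"] = (int)xp->tx_id.size(),
                      _["n_kmers"] = (double)xp->kmap.size(),
                      _["n_kmer_occurrences"] = (double)xp->n_kmer_occ,
                      _["n_ecs"] = (int)xp->ec_sets.size());
}

// [[Rcpp::export(name = ".index_tx_cpp")]]
List index_tx_cpp(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  CharacterVector gid(xp->tx_id.size());
  for (size_t i = 0; i < xp->tx_id.size(); ++i) gid[i] = xp->gene_id[xp->tx_gene[i]];
  return List::create(_["transcript_id"] = wrap(xp->tx_id),
                      _["gene_id"] = gid,
                      _["length"] = wrap(xp->tx_len));
}

static int align_one(KmerIndex& idx, const std::string& read, bool register_ec) {
  std::vector<int> cur;
  bool any = false, empty = false;
  for_each_kmer(read, idx.k, [&](uint64_t key) {
    if (empty) return;
    std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.kmap.find(key);
    if (it == idx.kmap.end()) return; // k-mers absent from the index are skipped
    if (!any) { cur = it->second; any = true; return; }
    // intersect sorted vectors in place
    const std::vector<int>& v = it->second;
    size_t a = 0, b = 0, w = 0;
    while (a < cur.size() && b < v.size()) {
      if (cur[a] < v[b]) ++a;
      else if (cur[a] > v[b]) ++b;
      else { cur[w++] = cur[a]; ++a; ++b; }
    }
    cur.resize(w);
    if (cur.empty()) empty = true;
  });
  if (!any || cur.empty()) return 0; // UNASSIGNED
  if (!register_ec) return -1;
  std::map<std::vector<int>, int>::iterator it = idx.ec_of_set.find(cur);
  if (it != idx.ec_of_set.end()) return it->second;
  int id = (int)idx.ec_sets.size() + 1;
  idx.ec_of_set[cur] = id;
  idx.ec_sets.push_back(cur);
  return id;
}

// Returns 1-based EC ids per read; 0 means unassigned. ECs are registered in
// the index in order of first observation.
// [[Rcpp::export(name = ".align_reads_cpp")]]
IntegerVector align_reads_cpp(SEXP xp_, CharacterVector reads) {
  XPtr<KmerIndex> xp(xp_);
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    if ((int)r.size() < xp->k)
      stop("read %d is shorter than k = %d", i + 1, xp->k);
    out[i] = align_one(*xp, r, true);
  }
  return out;
}

// [[Rcpp::export(name = ".ec_sets_cpp")]]
List ec_sets_cpp(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  int m = (int)xp->ec_sets.size();
  List out(m);
  for (int e = 0; e < m; ++e) {
    const std::vector<int>& v = xp->ec_sets[e];
    IntegerVector iv(v.size());
    for (size_t j = 0; j < v.size(); ++j) iv[j] = v[j] + 1; // 1-based tx index
    out[e] = iv;
  }
  return out;
}

// Draw `counts[t]` reads from transcript t: uniform start over len-L+1
// positions, i.i.d. substitutions at rate eps. Uses the R RNG stream.
// [[Rcpp::export(name = ".sim_reads_cpp")]]
List sim_reads_cpp(CharacterVector tx_seq, IntegerVector counts, int L, double eps) {
  RNGScope scope;
  static const char* BASES = "ACGT";
  long long total = 0;
  for (int t = 0; t < counts.size(); ++t) total += counts[t];
  CharacterVector reads(total);
  IntegerVector origin(total), start(total);
  long long r = 0;
  std::string buf;
  for (int t = 0; t < counts.size(); ++t) {
    if (counts[t] == 0) continue;
    std::string s = as<std::string>(tx_seq[t]);
    int npos = (int)s.size() - L + 1;
    if (npos < 1)
      stop("read length %d exceeds length of transcript %d", L, t + 1);
    for (int i = 0; i < counts[t]; ++i, ++r) {
      int st = (int)(unif_rand() * npos);
      if (st >= npos) st = npos - 1;
      buf.assign(s, st, L);
      if (eps > 0) {
        int nerr = (int)R::rbinom((double)L, eps);
        for (int e = 0; e < nerr; ++e) {
          int pos = (int)(unif_rand() * L);
          if (pos >= L) pos = L - 1;
          int b = base2bits(buf[pos]);
          int nb = (b + 1 + (int)(unif_rand() * 3)) % 4; // any of the 3 others
          buf[pos] = BASES[nb];
        }
      }
      reads[r] = buf;
      origin[r] = t + 1;
      start[r] = st; // 0-based
    }
  }
  return List::create(_["read"] = reads, _["origin"] = origin, _["start"] = start);
}

// EM for transcript abundances from one unit's TCC vector.
// Mixture over reads: component weight alpha_t/N, per-read density
// w_{e,t}/l_t where w_{e,t} is the number of start positions of t whose read
// falls in EC e (all-ones weights give the classic width-free EC EM).
// Update: alpha_t <- sum_e c_e * (alpha_t w_{e,t}/l_t) / sum_{t' in e} (alpha_{t'} w_{e,t'}/l_{t'})
// alpha sums to the assigned reads; the reported rho are molecule
// proportions, rho_t = (alpha_t/l_t) / sum(alpha/l); convergence on
// max |delta rho| < tol. Observed-data loglik =
// sum_e c_e log(sum_{t in e} (alpha_t/N) w_{e,t}/l_t).
// [[Rcpp::export(name = ".em_cpp")]]
List em_cpp(NumericVector ec_counts, List ec_tx, int n_tx,
            NumericVector eff_len, double tol, int max_iter,
            Nullable<List> ec_weights = R_NilValue) {
  int m = ec_counts.size();
  double N = 0;
  for (int e = 0; e < m; ++e) N += ec_counts[e];
  std::vector<std::vector<int> > sets(m);
  std::vector<std::vector<double> > wts(m);
  std::vector<bool> touched(n_tx, false);
  bool have_w = ec_weights.isNotNull();
  List wlist;
  if (have_w) wlist = List(ec_weights);
  for (int e = 0; e < m; ++e) {
    IntegerVector iv = ec_tx[e];
    sets[e].assign(iv.begin(), iv.end());
    if (have_w) {
      NumericVector wv = wlist[e];
      if ((int)wv.size() != (int)iv.size())
        stop("ec_weights[%d] length does not match its transcript set", e + 1);
      wts[e].assign(wv.begin(), wv.end());
    } else {
      wts[e].assign(iv.size(), 1.0);
    }
    for (size_t j = 0; j < sets[e].size(); ++j) {
      int t = sets[e][j] - 1;
      if (t < 0 || t >= n_tx) stop("EC %d references unknown transcript index", e + 1);
      sets[e][j] = t;
      if (ec_counts[e] > 0) touched[t] = true;
    }
  }
  std::vector<double> alpha(n_tx, 0.0), anew(n_tx), rho(n_tx, 0.0);
  if (N <= 0) {
    return List::create(_["alpha"] = wrap(alpha), _["rho"] = wrap(rho),
                        _["n_iter"] = 0, _["loglik"] = NumericVector(0),
                        _["converged"] = true);
  }
  int n_touch = 0;
  for (int t = 0; t < n_tx; ++t) if (touched[t]) ++n_touch;
  for (int t = 0; t < n_tx; ++t) alpha[t] = touched[t] ? N / n_touch : 0.0;
  std::vector<double> ll;
  ll.reserve(64);
  int it = 0;
  bool conv = false;
  for (it = 1; it <= max_iter; ++it) {
    std::fill(anew.begin(), anew.end(), 0.0);
    double llv = 0;
    for (int e = 0; e < m; ++e) {
      if (ec_counts[e] <= 0) continue;
      double denom = 0;
      for (size_t j = 0; j < sets[e].size(); ++j) {
        int t = sets[e][j];
        denom += alpha[t] * wts[e][j] / eff_len[t];
      }
      if (denom <= 0) continue;
      llv += ec_counts[e] * std::log(denom / N);
      for (size_t j = 0; j < sets[e].size(); ++j) {
        int t = sets[e][j];
        anew[t] += ec_counts[e] * (alpha[t] * wts[e][j] / eff_len[t]) / denom;
      }
    }
    ll.push_back(llv);
    // convergence on the mixture weights alpha/N: the quantity the EM
    // contracts geometrically (length-normalized proportions amplify noise
    // in short near-zero components and stall the stopping rule)
    double dmax = 0;
    for (int t = 0; t < n_tx; ++t) {
      double d = std::fabs(anew[t] - alpha[t]) / N;
      if (d > dmax) dmax = d;
    }
    alpha.swap(anew);
    if (dmax < tol) { conv = true; break; }
  }
  if (it > max_iter) it = max_iter;
  // reported proportions are molecule-scale: alpha/eff_len normalized
  {
    double s = 0;
    for (int t = 0; t < n_tx; ++t) { rho[t] = alpha[t] / eff_len[t]; s += rho[t]; }
    if (s > 0) for (int t = 0; t < n_tx; ++t) rho[t] /= s;
  }
  return List::create(_["alpha"] = wrap(alpha), _["rho"] = wrap(rho),
                      _["n_iter"] = it, _["loglik"] = wrap(ll),
                      _["converged"] = conv);
}

// Exact EC position widths: for every transcript, pseudoalign all of its
// reads of length L and count, per (EC, transcript), the number of start
// positions. Returns, aligned with the current EC registry, a list of
// per-EC numeric vectors parallel to the EC's transcript set.
// [[Rcpp::export(name = ".ec_widths_cpp")]]
List ec_widths_cpp(SEXP xp_, CharacterVector tx_seq, int L) {
  XPtr<KmerIndex> xp(xp_);
  int n_tx = tx_seq.size();
  if (n_tx != (int)xp->tx_id.size())
    stop("sequence set does not match the index");
  // pair (ec, t) counts, discovered on the fly
  std::map<std::pair<int, int>, double> w;
  std::string buf;
  for (int t = 0; t < n_tx; ++t) {
    std::string s = as<std::string>(tx_seq[t]);
    int npos = (int)s.size() - L + 1;
    for (int p = 0; p < npos; ++p) {
      buf.assign(s, p, L);
      int e = align_one(*xp, buf, true);
      if (e > 0) w[std::make_pair(e, t)] += 1.0;
    }
  }
  int m = (int)xp->ec_sets.size();
  List out(m);
  for (int e = 0; e < m; ++e) {
    const std::vector<int>& ts = xp->ec_sets[e];
    NumericVector wv(ts.size());
    for (size_t j = 0; j < ts.size(); ++j) {
      std::map<std::pair<int, int>, double>::iterator it =
        w.find(std::make_pair(e + 1, ts[j]));
      wv[j] = (it == w.end()) ? 0.0 : it->second;
    }
    out[e] = wv;
  }
  return out;
}
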