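#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdlib>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base encoding; 255 marks non-ACGT (IUPAC ambiguity or gap)
static inline uint8_t base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 255;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

struct Hit { int ref; long pos; };

typedef std::unordered_map<uint64_t, std::vector<Hit> > KmerIndex;

// exact k-mer index over every position of every reference (k <= 31)
static void index_refs(const std::vector<std::string>& refs, int k, KmerIndex& idx) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    if ((long)s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (long i = 0; i < (long)s.size(); ++i) {
      uint8_t b = base2bit(s[i]);
      if (b == 255) { valid = 0; key = 0; continue; }
      key = ((key << 2) | b) & mask;
      if (++valid >= k) idx[key].push_back(Hit{(int)r, i - k + 1});
    }
  }
}

// collect exact-match seed candidates for one oriented read
static void seed_candidates(const std::string& read, int k, const KmerIndex& idx,
                            std::vector<std::pair<int, long> >& cand) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  long n = (long)read.size();
  std::vector<long> offsets;
  for (long o = 0; o + k <= n; o += k) offsets.push_back(o);
  if (n - k > 0 && (offsets.empty() || offsets.back() != n - k)) offsets.push_back(n - k);
  for (long o : offsets) {
    uint64_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      uint8_t b = base2bit(read[o + j]);
      if (b == 255) { ok = false; break; }
      key = ((key << 2) | b) & mask;
    }
    if (!ok) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (const Hit& h : it->second) cand.push_back(std::make_pair(h.ref, h.pos - o));
  }
}

// ungapped comparison of an oriented read placed at ref position s (may be clipped)
static bool score_placement(const std::string& read, const std::string& ref, long s,
                            long& matches, long& overlap, long& clip_start) {
  long n = (long)read.size(), L = (long)ref.size();
  long a = s < 0 ? -s : 0;             // first read base used
  long b = (s + n > L) ? (L - s) : n;  // one past last read base used
  if (b <= a) return false;
  overlap = b - a;
  matches = 0;
  for (long i = a; i < b; ++i)
    if (base2bit(read[i]) == base2bit(ref[s + i]) && base2bit(read[i]) != 255) ++matches;
  clip_start = a;
  return true;
}

// Competitive read recruitment: exact k-mer seeding + ungapped extension on both
// strands; each read goes to the single best reference, ties broken uniformly
// at random with R's RNG (so set.seed() governs reproducibility).
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector refs, int k,
                   double min_identity, double min_aligned_fraction) {
  std::vector<std::string> R_(refs.size());
  for (int i = 0; i < refs.size(); ++i) R_[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  index_refs(R_, k, idx);

  int n = reads.size();
  IntegerVector ref_idx(n), ref_start(n), aln_len(n), edits(n);
  LogicalVector mapped(n);
  CharacterVector strand(n);

  struct Cand { int ref; long start; long matches; long overlap; long clip; char strand; };

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    long rl = (long)fwd.size();
    std::vector<Cand> best;
    long best_matches = -1;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& rd = ori == 0 ? fwd : rev;
      std::vector<std::pair<int, long> > cand;
      seed_candidates(rd, k, idx, cand);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto& c : cand) {
        long m, ov, clip;
        if (!score_placement(rd, R_[c.first], c.second, m, ov, clip)) continue;
        if ((double)ov / rl < min_aligned_fraction) continue;
        if ((double)m / ov < min_identity) continue;
        if (m > best_matches) {
          best_matches = m;
          best.clear();
        }
        if (m == best_matches)
          best.push_back(Cand{c.first, c.second + clip, m, ov, clip, ori == 0 ? '+' : '-'});
      }
    }
    if (best.empty()) {
      mapped[i] = false;
      ref_idx[i] = NA_INTEGER; ref_start[i] = NA_INTEGER;
      aln_len[i] = NA_INTEGER; edits[i] = NA_INTEGER; strand[i] = NA_STRING;
      continue;
    }
    // competitive tie-break: uniform over the distinct references tied at best
    std::vector<int> uref;
    for (auto& c : best)
      if (std::find(uref.begin(), uref.end(), c.ref) == uref.end()) uref.push_back(c.ref);
    int chosen_ref = uref[0];
    if (uref.size() > 1) {
      size_t pick = (size_t)(unif_rand() * uref.size());
      if (pick >= uref.size()) pick = uref.size() - 1;
      chosen_ref = uref[pick];
    }
    size_t wi = 0;
    while (best[wi].ref != chosen_ref) ++wi;
    const Cand& w = best[wi];
    mapped[i] = true;
    ref_idx[i] = w.ref + 1;
    ref_start[i] = (int)w.start;
    aln_len[i] = (int)w.overlap;
    edits[i] = (int)(w.overlap - w.matches);
    strand[i] = w.strand == '+' ? "+" : "-";
  }
  return List::create(_["ref_idx"] = ref_idx, _["ref_start"] = ref_start,
                      _["strand"] = strand, _["aligned_length"] = aln_len,
                      _["edit_distance"] = edits, _["is_mapped"] = mapped);
}

// banded global edit distance between two strings of similar length
static long banded_edit(const std::string& a, const std::string& b, int band) {
  long m = (long)a.size(), n = (long)b.size();
  if (labs(m - n) > band) return -1;
  const long INF = 1L << 30;
  std::vector<long> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // column j of row i lives at index j - i + band
  for (long j = 0; j <= band && j <= n; ++j) prev[j + band] = j;
  for (long i = 1; i <= m; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    long jlo = std::max(0L, i - band), jhi = std::min(n, i + band);
    for (long j = jlo; j <= jhi; ++j) {
      long k = j - i + band;
      long v = INF;
      if (j > 0 && k - 1 >= 0) { // deletion in b / gap: from (i, j-1)
        long w = cur[k - 1];
        if (w + 1 < v) v = w + 1;
      }
      if (k + 1 <= 2 * band) { // from (i-1, j): gap
        long w = prev[k + 1];
        if (w + 1 < v) v = w + 1;
      }
      if (j > 0) { // from (i-1, j-1): match/mismatch
        long w = prev[k];
        long cost = (base2bit(a[i - 1]) == base2bit(b[j - 1]) &&
                     base2bit(a[i - 1]) != 255) ? 0 : 1;
        if (w + cost < v) v = w + cost;
      } else {
        // j == 0: only vertical moves
        long w = prev[k + 1];
        if (w + 1 < v) v = w + 1;
      }
      cur[k] = v;
    }
    std::swap(prev, cur);
  }
  long res = prev[n - m + band];
  return res >= INF ? -1 : res;
}

// Fragment-based ANI: cut the query into consecutive fragments, anchor each by
// exact k-mer seed in the subject, extend with banded edit distance.
// Returns per-fragment identity (fraction) and subject coverage (fraction).
// [[Rcpp::export(name = ".fragment_ani_cpp")]]
List fragment_ani_cpp(CharacterVector fragments, CharacterVector subject,
                      int k, int band) {
  std::vector<std::string> S(1);
  S[0] = as<std::string>(subject[0]);
  KmerIndex idx;
  index_refs(S, k, idx);
  const std::string& ref = S[0];
  long L = (long)ref.size();

  int nf = fragments.size();
  NumericVector identity(nf), coverage(nf);
  IntegerVector aligned(nf);
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    long m = (long)frag.size();
    double best_id = -1, best_cov = 0;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string fr = ori == 0 ? frag : revcomp(frag);
      std::vector<std::pair<int, long> > cand;
      seed_candidates(fr, k, idx, cand);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto& c : cand) {
        long s = c.second;
        long a = std::max(0L, s), b = std::min(L, s + m);
        if (b <= a) continue;
        std::string win = ref.substr(a, b - a);
        std::string sub = fr.substr(a - s, b - a);
        long e = banded_edit(sub, win, band);
        if (e < 0) continue;
        double id = 1.0 - (double)e / (double)sub.size();
        double cov = (double)sub.size() / (double)m;
        if (id > best_id || (id == best_id && cov > best_cov)) {
          best_id = id; best_cov = cov;
        }
      }
    }
    if (best_id < 0) {
      identity[f] = NA_REAL; coverage[f] = 0; aligned[f] = 0;
    } else {
      identity[f] = best_id; coverage[f] = best_cov; aligned[f] = 1;
    }
  }
  return List::create(_["identity"] = identity, _["coverage"] = coverage,
                      _["aligned"] = aligned);
}
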