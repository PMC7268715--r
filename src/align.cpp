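#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Anchored guide-vs-candidate alignment.
//
// Both strings are written 5'->3' with the PAM-proximal base LAST (index
// L-1).  The PAM-proximal column is anchored: candidate extraction places
// the 20-mer flush against the PAM, so that base is compared positionally
// (anchored_match) and contributes no edit.  The remaining (L-1)-vs-(L-1)
// problem is a free global alignment under unit cost per mismatch /
// insertion / deletion.
//
// Edits are lexicographically minimised: first total edits, then the number
// of edits assigned to the seed region (guide positions 1..seed_len counted
// from the PAM; string index i is in the seed iff i >= L - seed_len,
// 0-based).  A mismatch or deletion is charged to the guide position it
// consumes; an insertion (gap in the guide) is charged to the adjacent
// PAM-proximal guide position.  Weights are encoded as 100*edits +
// seed_edits, valid while 2L < 100 (enforced in R: L <= 40).
static void align_anchored_one(const char *g, const char *c, int L,
                               int seed_len, int &total, int &seed_ed,
                               bool &anchored) {
  const int n = L - 1;        // PAM-distal subproblem length
  const int seed0 = L - seed_len; // 0-based string index threshold
  std::vector<int> prev(n + 1), cur(n + 1);

  prev[0] = 0;
  for (int j = 1; j <= n; ++j) {
    // j insertions before guide index 0
    int sj = (0 >= seed0) ? 1 : 0;
    prev[j] = prev[j - 1] + 100 + sj;
  }
  for (int i = 1; i <= n; ++i) {
    const int consume_seed = ((i - 1) >= seed0) ? 1 : 0; // guide index i-1
    cur[0] = prev[0] + 100 + consume_seed;               // deletion
    const int ins_seed = (i >= seed0) ? 1 : 0; // gap before guide index i
    for (int j = 1; j <= n; ++j) {
      int v = prev[j - 1] +
              ((g[i - 1] == c[j - 1]) ? 0 : (100 + consume_seed)); // sub
      int del = prev[j] + 100 + consume_seed;
      if (del < v) v = del;
      int ins = cur[j - 1] + 100 + ins_seed;
      if (ins < v) v = ins;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  total = prev[n] / 100;
  seed_ed = prev[n] % 100;
  anchored = (g[L - 1] == c[L - 1]);
}

// [[Rcpp::export]]
IntegerMatrix cpp_anchored_align(std::string guide, CharacterVector candidates,
                                 int seed_len) {
  const int L = (int)guide.size();
  if (L < 2 || L > 40) stop("guide length must be in [2, 40]");
  if (seed_len < 1 || seed_len >= L) stop("seed_len must be in [1, L-1]");
  const int nc = candidates.size();
  IntegerMatrix out(nc, 3);
  for (int k = 0; k < nc; ++k) {
    const char *c = CHAR(STRING_ELT(candidates, k));
    if ((int)std::strlen(c) != L)
      stop("candidate %d has length %d, expected %d", k + 1,
           (int)std::strlen(c), L);
    int total, seed_ed;
    bool anch;
    align_anchored_one(guide.c_str(), c, L, seed_len, total, seed_ed, anch);
    out(k, 0) = total;
    out(k, 1) = seed_ed;
    out(k, 2) = anch ? 1 : 0;
  }
  colnames(out) = CharacterVector::create("total_edits", "seed_edits",
                                          "anchored_match");
  return out;
}

static inline int base_code(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Off-target qualification under the seed-region criteria: the anchored base
// must match and the alignment must carry fewer than `ceiling` edits, or
// exactly `ceiling` edits all of which fall outside the seed region.
static inline bool qualifies(int total, int seed_ed, bool anch, int ceiling) {
  if (!anch) return false;
  if (total < ceiling) return true;
  return total == ceiling && seed_ed == 0;
}

// Batched per-reference scan: every guide against every candidate site.
// pam_class: 0 = NGG, 1 = NAG.  Prefilter: a qualifying site (<= ceiling
// edits against the guide) must share at least one exact `word`-mer with the
// guide (pigeonhole over untouched alignment segments); word is capped on
// the R side so the bound is lossless.  Returns per-guide qualifying-site
// counts split by PAM class and, optionally, the individual hits.
// [[Rcpp::export]]
List cpp_count_hits(CharacterVector guides, CharacterVector sites,
                    IntegerVector pam_class, int seed_len, int t_ngg,
                    int t_nag, bool prefilter, int word, bool collect_hits) {
  const int ng = guides.size(), ns = sites.size();
  IntegerMatrix counts(ng, 2);
  std::vector<int> hit_g, hit_s, hit_tot, hit_seed;

  int L = 0;
  if (ng > 0) L = (int)std::strlen(CHAR(STRING_ELT(guides, 0)));
  if (L > 0 && (L < 2 || L > 40)) stop("guide length must be in [2, 40]");

  const int nk = (word >= 1 && word <= L) ? (1 << (2 * word)) : 0;
  std::vector<unsigned char> mark(prefilter && nk > 0 ? nk : 0, 0);
  const int mask = nk > 0 ? nk - 1 : 0;

  // precompute site base codes and k-mer codes once
  std::vector<const char *> sptr(ns);
  for (int s = 0; s < ns; ++s) {
    sptr[s] = CHAR(STRING_ELT(sites, s));
    if ((int)std::strlen(sptr[s]) != L)
      stop("site %d has length %d, expected %d", s + 1,
           (int)std::strlen(sptr[s]), L);
  }

  for (int gi = 0; gi < ng; ++gi) {
    const char *g = CHAR(STRING_ELT(guides, gi));
    if ((int)std::strlen(g) != L)
      stop("guide %d has length %d, expected %d", gi + 1,
           (int)std::strlen(g), L);

    std::vector<int> gk; // guide k-mer codes, for unmarking
    if (prefilter && nk > 0) {
      int code = 0, valid = 0;
      for (int i = 0; i < L; ++i) {
        int b = base_code(g[i]);
        code = ((code << 2) | (b < 0 ? 0 : b)) & mask;
        valid = (b < 0) ? 0 : valid + 1;
        if (valid >= word && !mark[code]) {
          mark[code] = 1;
          gk.push_back(code);
        }
      }
    }

    for (int s = 0; s < ns; ++s) {
      const char *c = sptr[s];
      if (prefilter && nk > 0) {
        bool shared = false;
        int code = 0, valid = 0;
        for (int i = 0; i < L && !shared; ++i) {
          int b = base_code(c[i]);
          code = ((code << 2) | (b < 0 ? 0 : b)) & mask;
          valid = (b < 0) ? 0 : valid + 1;
          if (valid >= word && mark[code]) shared = true;
        }
        if (!shared) continue;
      }
      int total, seed_ed;
      bool anch;
      align_anchored_one(g, c, L, seed_len, total, seed_ed, anch);
      const int ceiling = (pam_class[s] == 0) ? t_ngg : t_nag;
      if (qualifies(total, seed_ed, anch, ceiling)) {
        counts(gi, pam_class[s] == 0 ? 0 : 1)++;
        if (collect_hits) {
          hit_g.push_back(gi + 1);
          hit_s.push_back(s + 1);
          hit_tot.push_back(total);
          hit_seed.push_back(seed_ed);
        }
      }
    }

    for (size_t k = 0; k < gk.size(); ++k) mark[gk[k]] = 0;
  }

  List hits = List::create(_["guide_idx"] = wrap(hit_g),
                           _["site_idx"] = wrap(hit_s),
                           _["total_edits"] = wrap(hit_tot),
                           _["seed_edits"] = wrap(hit_seed));
  return List::create(_["counts"] = counts, _["hits"] = hits);
}
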