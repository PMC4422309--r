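#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// Ungapped alignment primitives shared by the consensus prefix scan and the
// seed-and-extend genomic mapper. Sequences arrive as plain upper-case
// character strings; 'N' never matches anything (including another 'N').

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// mismatches of q placed at ref[pos..pos+len), early exit above cap
static inline int count_mm(const char *q, const char *ref, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (!base_match(q[i], ref[i])) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

// ---------------------------------------------------------------------------
// Consensus prefix scan: every read prefix against every reference, both
// strands, every offset, all placements with <= max_mm mismatches reported.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_scan_prefix(CharacterVector reads, CharacterVector refs,
                          int max_mm) {
  std::vector<std::string> rf(refs.size());
  for (int i = 0; i < refs.size(); ++i) rf[i] = as<std::string>(refs[i]);

  std::vector<int> o_read, o_ref, o_start, o_mm;
  std::vector<std::string> o_strand;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    int L = (int) fwd.size();
    if (L == 0) continue;
    for (int f = 0; f < (int) rf.size(); ++f) {
      int reflen = (int) rf[f].size();
      const char *refp = rf[f].c_str();
      for (int strand = 0; strand < 2; ++strand) {
        const char *q = strand == 0 ? fwd.c_str() : rev.c_str();
        for (int off = 0; off + L <= reflen; ++off) {
          int mm = count_mm(q, refp + off, L, max_mm);
          if (mm <= max_mm) {
            o_read.push_back(r + 1);
            o_ref.push_back(f + 1);
            o_start.push_back(off + 1);
            o_strand.push_back(strand == 0 ? "+" : "-");
            o_mm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
    _["start"] = wrap(o_start), _["strand"] = wrap(o_strand),
    _["mismatches"] = wrap(o_mm), _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Seed-and-extend genomic mapper with optional single-junction split mode.
// ---------------------------------------------------------------------------

struct Placement {          // contiguous candidate
  long g;                   // global start
  int strand;               // 0 +, 1 -
  int mm;
};

struct SplitBest {
  long d1, d2;
  int a;                    // split point (prefix length)
  int mm;
  bool canonical;
  int motif;                // 0 '+', 1 '-', 2 none
  int strand;
  bool valid;
};

// 2-bit encode, code 4 for N
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector chrom_seqs,
                        int seed_len, int max_mm, int min_unique_gap,
                        int min_anchor, int max_intron, int min_intron,
                        bool try_split) {
  const int k = seed_len;
  const int n_chrom = chrom_seqs.size();

  // concatenated genome with per-chromosome offsets
  std::vector<long> cstart(n_chrom + 1, 0);
  std::string gen;
  {
    long tot = 0;
    for (int c = 0; c < n_chrom; ++c) {
      tot += LENGTH(STRING_ELT(chrom_seqs, c));
      cstart[c + 1] = tot;
    }
    gen.reserve(tot);
    for (int c = 0; c < n_chrom; ++c) gen += as<std::string>(chrom_seqs[c]);
  }
  const long G = (long) gen.size();
  const char *gp = gen.c_str();

  // exact k-mer index (counting sort over 4^k buckets)
  const long nbuck = 1L << (2 * k);
  std::vector<uint32_t> bucket_end(nbuck + 1, 0);
  std::vector<uint32_t> kmer_of(G >= k ? G - k + 1 : 0);
  const uint32_t BAD = 0xFFFFFFFFu;
  {
    uint32_t key = 0; int bad = k; // bad counts positions since last N
    for (long i = 0; i < G; ++i) {
      int b = base_code(gp[i]);
      key = ((key << 2) | (b & 3)) & (uint32_t)(nbuck - 1);
      bad = (b == 4) ? 0 : bad + 1;
      if (i >= k - 1) {
        long p = i - k + 1;
        // crossing a chromosome boundary invalidates the k-mer
        bool cross = false;
        for (int c = 1; c < n_chrom; ++c)
          if (cstart[c] > p && cstart[c] < p + k) { cross = true; break; }
        if (bad >= k && !cross) { kmer_of[p] = key; bucket_end[key + 1]++; }
        else kmer_of[p] = BAD;
      }
    }
    for (long b = 0; b < nbuck; ++b) bucket_end[b + 1] += bucket_end[b];
  }
  std::vector<uint32_t> pos_sorted(kmer_of.empty() ? 0 : bucket_end[nbuck]);
  {
    std::vector<uint32_t> cur(bucket_end.begin(), bucket_end.end() - 1);
    for (long p = 0; p < (long) kmer_of.size(); ++p)
      if (kmer_of[p] != BAD) pos_sorted[cur[kmer_of[p]]++] = (uint32_t) p;
  }

  // secondary index of min_anchor-length words: split-mode anchors can be
  // shorter than the main seed, so terminal mini-seeds discover them
  const int k2 = std::min(min_anchor, k);
  std::vector<uint32_t> b2_end, pos2;
  if (try_split && k2 >= 4 && k2 < k) {
    const long nb2 = 1L << (2 * k2);
    b2_end.assign(nb2 + 1, 0);
    std::vector<uint32_t> kmer2(G >= k2 ? G - k2 + 1 : 0, 0xFFFFFFFFu);
    uint32_t key = 0; int bad = k2;
    for (long i = 0; i < G; ++i) {
      int b = base_code(gp[i]);
      key = ((key << 2) | (b & 3)) & (uint32_t)(nb2 - 1);
      bad = (b == 4) ? 0 : bad + 1;
      if (i >= k2 - 1) {
        long p = i - k2 + 1;
        bool cross = false;
        for (int c = 1; c < n_chrom; ++c)
          if (cstart[c] > p && cstart[c] < p + k2) { cross = true; break; }
        if (bad >= k2 && !cross) { kmer2[p] = key; b2_end[key + 1]++; }
      }
    }
    for (long b = 0; b < nb2; ++b) b2_end[b + 1] += b2_end[b];
    pos2.assign(kmer2.empty() ? 0 : b2_end[nb2], 0);
    std::vector<uint32_t> cur(b2_end.begin(), b2_end.end() - 1);
    for (long p = 0; p < (long) kmer2.size(); ++p)
      if (kmer2[p] != 0xFFFFFFFFu) pos2[cur[kmer2[p]]++] = (uint32_t) p;
  }

  auto chrom_of = [&](long g) {
    int lo = 0, hi = n_chrom;
    while (hi - lo > 1) { int m = (lo + hi) / 2; if (cstart[m] <= g) lo = m; else hi = m; }
    return lo;
  };

  std::vector<int> o_read, o_s1, o_e1, o_s2, o_e2, o_mm, o_chrom;
  std::vector<int> o_unique;
  std::vector<std::string> o_strand, o_motif;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int L = (int) fwd.size();
    if (L < k) continue;
    std::string rev = revcomp(fwd);
    const std::string *seq[2] = { &fwd, &rev };

    // seed offsets: every k, plus the final window
    std::vector<int> qoff;
    for (int q = 0; q + k <= L; q += k) qoff.push_back(q);
    if (qoff.empty() || qoff.back() != L - k) qoff.push_back(L - k);

    // candidate diagonals per strand (global "virtual read start" positions)
    std::vector<long> diags[2];
    for (int s = 0; s < 2; ++s) {
      const char *q = seq[s]->c_str();
      std::unordered_set<long> seen;
      for (int qo : qoff) {
        uint32_t key = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int b = base_code(q[qo + i]);
          if (b == 4) { ok = false; break; }
          key = (key << 2) | (uint32_t) b;
        }
        if (!ok) continue;
        for (uint32_t idx = bucket_end[key]; idx < bucket_end[key + 1]; ++idx) {
          long d = (long) pos_sorted[idx] - qo;
          if (seen.insert(d).second) diags[s].push_back(d);
        }
      }
      std::sort(diags[s].begin(), diags[s].end());
    }

    // ---- contiguous placements
    const int cap = max_mm + min_unique_gap;
    std::vector<Placement> plc;
    int best_mm = cap + 1, second_mm = cap + 1;
    for (int s = 0; s < 2; ++s) {
      const char *q = seq[s]->c_str();
      for (long d : diags[s]) {
        if (d < 0 || d + L > G) continue;
        int c = chrom_of(d);
        if (d + L > cstart[c + 1]) continue; // spans chromosome boundary
        int mm = count_mm(q, gp + d, L, cap);
        plc.push_back({d, s, mm});
        if (mm < best_mm) { second_mm = best_mm; best_mm = mm; }
        else if (mm < second_mm) second_mm = mm;
      }
    }

    bool any_contig = best_mm <= max_mm;
    if (any_contig) {
      // count placements achieving best_mm
      int n_best = 0;
      for (auto &p : plc) if (p.mm == best_mm) ++n_best;
      for (auto &p : plc) {
        if (p.mm > max_mm) continue;
        int c = chrom_of(p.g);
        bool uniq = (p.mm == best_mm) && n_best == 1 &&
                    (second_mm - best_mm) >= min_unique_gap;
        o_read.push_back(r + 1);
        o_chrom.push_back(c + 1);
        o_strand.push_back(p.strand == 0 ? "+" : "-");
        o_s1.push_back((int)(p.g - cstart[c] + 1));
        o_e1.push_back((int)(p.g - cstart[c] + L));
        o_s2.push_back(NA_INTEGER);
        o_e2.push_back(NA_INTEGER);
        o_mm.push_back(p.mm);
        o_unique.push_back(uniq ? 1 : 0);
        o_motif.push_back(".");
      }
      continue;
    }

    // ---- split mode
    if (!try_split || L < 2 * min_anchor) continue;

    // augment candidate diagonals with terminal mini-seed hits
    if (!b2_end.empty() && L >= k2) {
      for (int s = 0; s < 2; ++s) {
        const char *q = seq[s]->c_str();
        std::unordered_set<long> seen(diags[s].begin(), diags[s].end());
        for (int qo : {0, L - k2}) {
          uint32_t key = 0; bool ok = true;
          for (int i = 0; i < k2; ++i) {
            int b = base_code(q[qo + i]);
            if (b == 4) { ok = false; break; }
            key = (key << 2) | (uint32_t) b;
          }
          if (!ok) continue;
          for (uint32_t idx = b2_end[key]; idx < b2_end[key + 1]; ++idx) {
            long d = (long) pos2[idx] - qo;
            if (seen.insert(d).second) diags[s].push_back(d);
          }
        }
        std::sort(diags[s].begin(), diags[s].end());
      }
    }

    SplitBest best; best.valid = false; best.mm = cap + 1;
    int split_second = cap + 1;                 // best mm among other diag pairs
    if (best_mm < split_second) split_second = best_mm; // contiguous competitor
    std::vector<int> P(L + 1), S(L + 1);

    for (int s = 0; s < 2; ++s) {
      const char *q = seq[s]->c_str();
      const std::vector<long> &D = diags[s];
      for (size_t i = 0; i < D.size(); ++i) {
        long d1 = D[i];
        if (d1 < 0 || d1 + L > G) continue;
        int c1 = chrom_of(d1);
        if (d1 + L > cstart[c1 + 1]) continue;
        bool haveP = false;
        for (size_t j = i + 1; j < D.size(); ++j) {
          long d2 = D[j];
          long gap = d2 - d1;
          if (gap < min_intron) continue;
          if (gap > max_intron) break;
          if (d2 + L > G) continue;
          int c2 = chrom_of(d2);
          if (c2 != c1 || d2 + L > cstart[c2 + 1]) continue;
          if (!haveP) {
            P[0] = 0;
            for (int x = 0; x < L; ++x)
              P[x + 1] = P[x] + (base_match(q[x], gp[d1 + x]) ? 0 : 1);
            haveP = true;
          }
          S[L] = 0;
          for (int x = L - 1; x >= 0; --x)
            S[x] = S[x + 1] + (base_match(q[x], gp[d2 + x]) ? 0 : 1);
          // best split point for this diagonal pair
          int pb_mm = cap + 1, pb_a = -1; bool pb_canon = false; int pb_motif = 2;
          for (int a = min_anchor; a <= L - min_anchor; ++a) {
            int tot = P[a] + S[a];
            if (tot > max_mm) continue;
            long is = d1 + a, ie = d2 + a; // intron [is, ie) global, 0-based
            bool canon_p = gp[is] == 'G' && gp[is + 1] == 'T' &&
                           gp[ie - 2] == 'A' && gp[ie - 1] == 'G';
            bool canon_m = gp[is] == 'C' && gp[is + 1] == 'T' &&
                           gp[ie - 2] == 'A' && gp[ie - 1] == 'C';
            bool canon = canon_p || canon_m;
            if (tot < pb_mm || (tot == pb_mm && canon && !pb_canon)) {
              pb_mm = tot; pb_a = a; pb_canon = canon;
              pb_motif = canon_p ? 0 : (canon_m ? 1 : 2);
            }
          }
          if (pb_a < 0) continue;
          if (pb_mm < best.mm ||
              (pb_mm == best.mm && pb_canon && !best.canonical)) {
            if (best.valid && best.mm < split_second) split_second = best.mm;
            best.valid = true; best.d1 = d1; best.d2 = d2; best.a = pb_a;
            best.mm = pb_mm; best.canonical = pb_canon; best.motif = pb_motif;
            best.strand = s;
          } else if (pb_mm < split_second) {
            split_second = pb_mm;
          }
        }
      }
    }

    if (best.valid && best.mm <= max_mm) {
      int c = chrom_of(best.d1);
      bool uniq = (split_second - best.mm) >= min_unique_gap;
      o_read.push_back(r + 1);
      o_chrom.push_back(c + 1);
      o_strand.push_back(best.strand == 0 ? "+" : "-");
      o_s1.push_back((int)(best.d1 - cstart[c] + 1));
      o_e1.push_back((int)(best.d1 - cstart[c] + best.a));
      o_s2.push_back((int)(best.d2 - cstart[c] + best.a + 1));
      o_e2.push_back((int)(best.d2 - cstart[c] + L));
      o_mm.push_back(best.mm);
      o_unique.push_back(uniq ? 1 : 0);
      o_motif.push_back(best.motif == 0 ? "+" : (best.motif == 1 ? "-" : "."));
    }
  }

  return DataFrame::create(
    _["read"] = wrap(o_read), _["chrom"] = wrap(o_chrom),
    _["strand"] = wrap(o_strand),
    _["start1"] = wrap(o_s1), _["end1"] = wrap(o_e1),
    _["start2"] = wrap(o_s2), _["end2"] = wrap(o_e2),
    _["mismatches"] = wrap(o_mm), _["unique"] = wrap(o_unique),
    _["motif_strand"] = wrap(o_motif), _["stringsAsFactors"] = false);
}
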