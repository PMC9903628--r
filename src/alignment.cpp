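#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Alignment core for the msGBS workflow.
//
// Conventions shared by all routines:
//  * sequences are uppercase; any character outside {A,C,G,T} (notably the
//    N used as joined-read spacer) never matches anything, including itself;
//  * global identity is 1 - d/max(len) with d the unit-cost edit distance,
//    which coincides with matches/alignment-length for the equal-length,
//    substitution-only comparisons that dominate GBS clusters;
//  * the mapping score of a read against a cluster is
//    (read length - semi-global edit distance) / read length, i.e. the
//    reference may absorb free leading/trailing gaps but the read aligns
//    end to end.

static inline bool base_match(char a, char b) {
    if (a != b) return false;
    return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
    R_xlen_t n = x.size();
    CharacterVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        out[i] = revcomp_str(as<std::string>(x[i]));
    }
    return out;
}

// Banded global (Needleman-Wunsch, unit costs) edit distance.
// Returns the exact distance if it is <= kmax, otherwise kmax + 1.
static int lev_banded(const std::string &a, const std::string &b, int kmax) {
    const int n = (int) a.size(), m = (int) b.size();
    if (kmax < 0) return kmax + 1;
    if (std::abs(n - m) > kmax) return kmax + 1;
    const int INF = kmax + 1;
    // band of half-width kmax around the diagonal; cells just outside the
    // band carry INF sentinels so reads from the previous row stay valid
    std::vector<int> prev(m + 2, INF), cur(m + 2, INF);
    for (int j = 0; j <= std::min(m, kmax); ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        int lo = std::max(1, i - kmax), hi = std::min(m, i + kmax);
        cur[lo - 1] = (lo == 1 && i <= kmax) ? i : INF;
        int rowmin = INF;
        for (int j = lo; j <= hi; ++j) {
            int d = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
            if (prev[j] + 1 < d) d = prev[j] + 1;
            if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
            if (d > INF) d = INF;
            cur[j] = d;
            if (d < rowmin) rowmin = d;
        }
        if (rowmin >= INF) return INF;  // the whole band exceeded kmax
        cur[hi + 1] = INF;
        std::swap(prev, cur);
    }
    return std::min(prev[m], INF);
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
    int kmax = (int) std::max(a.size(), b.size());
    return lev_banded(a, b, kmax);
}

// [[Rcpp::export]]
double cpp_seq_identity(std::string a, std::string b) {
    size_t mx = std::max(a.size(), b.size());
    if (mx == 0) stop("identity of two empty sequences is undefined");
    return 1.0 - (double) cpp_edit_distance(a, b) / (double) mx;
}

// Semi-global edit distance: pattern p aligned end-to-end, text t with free
// leading/trailing gaps. Ukkonen row cutoff; exact when <= kmax else kmax+1.
static int infix_bounded(const std::string &p, const std::string &t, int kmax) {
    const int n = (int) p.size(), m = (int) t.size();
    if (n == 0) return 0;
    const int INF = kmax + 1;
    if (kmax < 0) return INF;
    std::vector<int> prev(n + 1), cur(n + 1);
    for (int i = 0; i <= n; ++i) prev[i] = i;           // column j = 0
    int lact = std::min(n, kmax);                        // last active row
    int best = (n <= kmax) ? n : INF;
    for (int j = 1; j <= m; ++j) {
        cur[0] = 0;                                      // free text prefix
        int lim = std::min(n, lact + 1);
        for (int i = 1; i <= lim; ++i) {
            int d = prev[i - 1] + (base_match(p[i - 1], t[j - 1]) ? 0 : 1);
            int up = (i - 1 <= lim) ? cur[i - 1] + 1 : INF;
            if (up < d) d = up;
            if (prev[i] + 1 < d) d = prev[i] + 1;
            cur[i] = d > INF ? INF : d;
        }
        if (lim + 1 <= n) cur[lim + 1] = INF;  // guard row for next column
        lact = lim;
        while (lact > 0 && cur[lact] > kmax) --lact;
        if (lim == n && cur[n] < best) best = cur[n];
        std::swap(prev, cur);
        if (best == 0) return 0;
    }
    return std::min(best, INF);
}

// [[Rcpp::export]]
int cpp_infix_distance(std::string pattern, std::string text, int kmax) {
    if (kmax < 0 || kmax > (int) std::max(pattern.size(), text.size()))
        kmax = (int) std::max(pattern.size(), text.size());
    return infix_bounded(pattern, text, kmax);
}

// Split a (possibly joined) read at the first run of >= spacer_len N's.
static void split_spacer(const std::string &s, int spacer_len,
                         std::vector<std::string> &parts) {
    parts.clear();
    size_t run = 0, start = 0;
    for (size_t i = 0; i <= s.size(); ++i) {
        if (i < s.size() && s[i] == 'N') { ++run; continue; }
        if (run >= (size_t) spacer_len) {
            size_t spacer_start = i - run;
            if (spacer_start > start)
                parts.push_back(s.substr(start, spacer_start - start));
            start = i;
        }
        run = 0;
    }
    if (start < s.size()) parts.push_back(s.substr(start));
    if (parts.empty()) parts.push_back(s);
}

// Matches of a read (joined reads pooled over their two halves) against one
// reference, for a fixed orientation. Returns -1 when the total distance
// exceeds the budget (so the candidate cannot reach the required matches).
static int read_matches(const std::vector<std::string> &parts, int eff_len,
                        const std::string &ref, int kmax_total) {
    // cheap length-based lower bound on the total distance
    int lb = 0;
    for (size_t h = 0; h < parts.size(); ++h)
        lb += std::max(0, (int) parts[h].size() - (int) ref.size());
    if (lb > kmax_total) return -1;
    int dtot = 0;
    for (size_t h = 0; h < parts.size(); ++h) {
        int budget = kmax_total - dtot;
        if (budget < 0) return -1;
        int d = infix_bounded(parts[h], ref, budget);
        if (d > budget) return -1;
        dtot += d;
    }
    return eff_len - dtot;
}

static inline uint64_t encode_base(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;
    }
}

// Roll k-mers of a string into codes; positions containing non-ACGT get -1.
static void kmer_codes(const std::string &s, int k, std::vector<int64_t> &out) {
    out.clear();
    if ((int) s.size() < k) return;
    uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
        uint64_t b = encode_base(s[i]);
        if (b > 3) { valid = 0; code = 0; }
        else { code = ((code << 2) | b) & mask; ++valid; }
        if ((int) i >= k - 1) out.push_back(valid >= k ? (int64_t) code : -1);
    }
}

// Greedy centroid clustering. seqs must already be ordered (size-descending,
// ties lexicographic). Returns the 1-based index (into seqs) of the centroid
// each sequence was assigned to; a sequence founding a cluster points to
// itself.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double identity,
                                 bool both_strands) {
    if (identity <= 0.0 || identity > 1.0)
        stop("identity must be in (0, 1]");
    int n = seqs.size();
    IntegerVector assign(n);
    std::vector<std::string> cent;       // centroid sequences
    std::vector<std::string> cent_rc;
    std::vector<int> cent_idx;           // 1-based index of centroid in seqs
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int hit = 0;
        for (size_t c = 0; c < cent.size() && !hit; ++c) {
            size_t mx = std::max(s.size(), cent[c].size());
            int kmax = (int) std::floor((1.0 - identity) * (double) mx + 1e-9);
            if ((int) (mx - std::min(s.size(), cent[c].size())) > kmax)
                continue;
            if (lev_banded(s, cent[c], kmax) <= kmax) { hit = cent_idx[c]; break; }
            if (both_strands &&
                lev_banded(s, cent_rc[c], kmax) <= kmax) { hit = cent_idx[c]; break; }
        }
        if (hit) {
            assign[i] = hit;
        } else {
            cent.push_back(s);
            cent_rc.push_back(revcomp_str(s));
            cent_idx.push_back(i + 1);
            assign[i] = i + 1;
        }
    }
    return assign;
}

// Overlap-merge of read pairs. mate2 is reverse-complemented, then the
// longest suffix(mate1)/prefix(rc mate2) overlap with length >= min_overlap
// and mismatch fraction <= max_mm_frac is merged (consensus base from
// mate1); otherwise the pair is joined with the given spacer.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector mate1, CharacterVector mate2,
                     int min_overlap, double max_mm_frac, std::string spacer) {
    R_xlen_t n = mate1.size();
    if (mate2.size() != n) stop("mate vectors differ in length");
    CharacterVector seq(n);
    LogicalVector merged(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string m1 = as<std::string>(mate1[r]);
        std::string rc2 = revcomp_str(as<std::string>(mate2[r]));
        int l1 = (int) m1.size(), l2 = (int) rc2.size();
        int omax = std::min(l1, l2);
        int found = 0;
        for (int o = omax; o >= min_overlap && o >= 1; --o) {
            int mm = 0, allowed = (int) std::floor(max_mm_frac * o + 1e-9);
            for (int p = 0; p < o && mm <= allowed; ++p)
                if (!base_match(m1[l1 - o + p], rc2[p])) ++mm;
            if (mm <= allowed) { found = o; break; }
        }
        if (found > 0) {
            seq[r] = m1 + rc2.substr(found);
            merged[r] = true;
        } else {
            seq[r] = m1 + spacer + rc2;
            merged[r] = false;
        }
    }
    return List::create(_["sequence"] = seq, _["merged"] = merged);
}

// Assign observed barcode strings to a barcode table within max_mm
// mismatches (Hamming, equal length). Returns 1-based index, 0 = unassigned.
// [[Rcpp::export]]
IntegerVector cpp_match_barcodes(CharacterVector observed,
                                 CharacterVector barcodes, int max_mm) {
    int nb = barcodes.size();
    std::vector<std::string> bc(nb);
    for (int b = 0; b < nb; ++b) bc[b] = as<std::string>(barcodes[b]);
    R_xlen_t n = observed.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string o = as<std::string>(observed[i]);
        int hit = 0;
        for (int b = 0; b < nb; ++b) {
            if (bc[b].size() != o.size()) continue;
            int mm = 0;
            for (size_t p = 0; p < o.size() && mm <= max_mm; ++p)
                if (!base_match(o[p], bc[b][p])) ++mm;
            if (mm <= max_mm) { hit = b + 1; break; }
        }
        out[i] = hit;
    }
    return out;
}

// Map reads against reference centroids. Per read, every reference whose
// score reaches score_min AND ties the read's best score is reported
// (tie tolerance zero, on integer match counts). Joined reads (internal
// N-run spacer of length spacer_len) are scored as two pooled half
// alignments normalised by the non-spacer length. Both orientations of the
// read are tried. When exhaustive = false, candidate references are
// shortlisted by shared k-mers (k = kmer); reads sharing no k-mer with any
// reference are reported unmapped.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs,
                   double score_min, int max_hits, bool exhaustive,
                   int kmer, int spacer_len) {
    const int nref = refs.size();
    std::vector<std::string> rf(nref);
    for (int j = 0; j < nref; ++j) rf[j] = as<std::string>(refs[j]);

    // k-mer index over references (forward strand of the centroid).
    std::unordered_map<uint64_t, std::vector<int> > index;
    if (!exhaustive) {
        std::vector<int64_t> codes;
        for (int j = 0; j < nref; ++j) {
            kmer_codes(rf[j], kmer, codes);
            for (size_t p = 0; p < codes.size(); ++p) {
                if (codes[p] < 0) continue;
                std::vector<int> &v = index[(uint64_t) codes[p]];
                if (v.empty() || v.back() != j) v.push_back(j);
            }
        }
    }

    const R_xlen_t n = reads.size();
    List hits(n);
    NumericVector best_score(n);
    LogicalVector dropped(n);
    std::vector<int64_t> codes;
    // per candidate: shared-k-mer tally per strand (forward read / revcomp)
    std::unordered_map<int, std::pair<int, int> > cand;

    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        std::string src = revcomp_str(s);
        std::vector<std::string> parts_f, parts_r;
        split_spacer(s, spacer_len, parts_f);
        split_spacer(src, spacer_len, parts_r);
        int eff_len = 0;
        for (size_t h = 0; h < parts_f.size(); ++h)
            eff_len += (int) parts_f[h].size();
        // minimal match count a retained event needs
        int minmatch = (int) std::ceil(score_min * eff_len - 1e-9);
        if (minmatch < 0) minmatch = 0;

        // valid k-mer positions per strand (q-gram lemma denominator):
        // an alignment with d edits preserves >= V - k*d read k-mers, so
        // a reference sharing fewer can be excluded without aligning it
        int vf = 0, vr = 0;
        cand.clear();
        if (!exhaustive) {
            for (int strand = 1; strand <= 2; ++strand) {
                kmer_codes(strand == 1 ? s : src, kmer, codes);
                int valid = 0;
                for (size_t p = 0; p < codes.size(); ++p) {
                    if (codes[p] < 0) continue;
                    ++valid;
                    std::unordered_map<uint64_t, std::vector<int> >::iterator
                        it = index.find((uint64_t) codes[p]);
                    if (it == index.end()) continue;
                    for (size_t q = 0; q < it->second.size(); ++q) {
                        std::pair<int, int> &e = cand[it->second[q]];
                        if (strand == 1) e.first += 1; else e.second += 1;
                    }
                }
                if (strand == 1) vf = valid; else vr = valid;
            }
        }
        // most-supported candidates first, so the shrinking match budget
        // below prunes the homolog alignments cheaply
        std::vector<std::pair<int, int> > order;  // (-max kmer hits, ref)
        if (exhaustive) {
            order.reserve(nref);
            for (int j = 0; j < nref; ++j)
                order.push_back(std::make_pair(0, j));
        } else {
            order.reserve(cand.size());
            for (std::unordered_map<int, std::pair<int, int> >::iterator it =
                     cand.begin(); it != cand.end(); ++it)
                order.push_back(std::make_pair(
                    -std::max(it->second.first, it->second.second),
                    it->first));
            std::sort(order.begin(), order.end());
        }

        int best = minmatch - 1;  // events must reach at least minmatch
        std::vector<int> best_refs;
        for (size_t c = 0; c < order.size(); ++c) {
            int j = order[c].second;
            int hf = 3, hr = 3;  // exhaustive: align both strands
            if (!exhaustive) {
                std::pair<int, int> &e = cand[j];
                hf = e.first; hr = e.second;
            }
            // only distances small enough to reach max(best, minmatch)
            // matches can matter; everything beyond is pruned in the DP
            int d_allow = eff_len - std::max(best, minmatch);
            int m = -1;
            bool try_f = exhaustive || hf >= vf - kmer * d_allow;
            bool try_r = exhaustive || hr >= vr - kmer * d_allow;
            if (try_f) {
                int mf = read_matches(parts_f, eff_len, rf[j], d_allow);
                if (mf > m) m = mf;
            }
            if (try_r) {
                int mr = read_matches(parts_r, eff_len, rf[j], d_allow);
                if (mr > m) m = mr;
            }
            if (m < 0) continue;
            if (m > best) { best = m; best_refs.clear(); }
            if (m == best) best_refs.push_back(j + 1);
        }

        // exhaustive-equivalence guard: references sharing no k-mer were
        // skipped above; they are excluded by the q-gram bound only when
        // 0 < V - k * d_allow on both strands. Otherwise align them too.
        if (!exhaustive) {
            int d_allow = eff_len - std::max(best, minmatch);
            if (vf - kmer * d_allow <= 0 || vr - kmer * d_allow <= 0) {
                for (int j = 0; j < nref; ++j) {
                    if (cand.find(j) != cand.end()) continue;
                    int d_now = eff_len - std::max(best, minmatch);
                    int m = -1;
                    int mf = read_matches(parts_f, eff_len, rf[j], d_now);
                    if (mf > m) m = mf;
                    int mr = read_matches(parts_r, eff_len, rf[j], d_now);
                    if (mr > m) m = mr;
                    if (m < 0) continue;
                    if (m > best) { best = m; best_refs.clear(); }
                    if (m == best) best_refs.push_back(j + 1);
                }
            }
        }

        if (best < minmatch || best_refs.empty()) {
            hits[i] = IntegerVector(0);
            best_score[i] = NA_REAL;
        } else if ((int) best_refs.size() > max_hits) {
            hits[i] = IntegerVector(0);
            best_score[i] = (double) best / eff_len;
            dropped[i] = true;
        } else {
            std::sort(best_refs.begin(), best_refs.end());
            hits[i] = wrap(best_refs);
            best_score[i] = (double) best / eff_len;
        }
    }
    return List::create(_["hits"] = hits, _["score"] = best_score,
                        _["dropped"] = dropped);
}

// Mutate sequences at given (1-based) positions to the supplied bases.
// Used by the genome simulator; vectorised here because R string surgery on
// hundreds of kb is slow.
// [[Rcpp::export]]
std::string cpp_substitute(std::string s, IntegerVector pos,
                           CharacterVector base) {
    if (pos.size() != base.size()) stop("pos/base length mismatch");
    for (R_xlen_t i = 0; i < pos.size(); ++i) {
        int p = pos[i];
        if (p < 1 || p > (int) s.size()) stop("substitution out of range");
        s[p - 1] = as<std::string>(base[i])[0];
    }
    return s;
}
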