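#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// Ungapped sense-strand Hamming matching of probes against transcripts:
// every alignment with at most max_mm mismatches is reported. Uses exact
// pigeonhole seeding (an alignment with <= m mismatches leaves at least one
// of m+1 probe segments exact), verified by full Hamming comparison, so the
// hit set equals a brute-force scan. Falls back to the plain scan when the
// probes are too short to seed.
// [[Rcpp::export]]
DataFrame cpp_probe_hits(CharacterVector probes, CharacterVector transcripts,
                         int max_mm) {
  std::vector<int> out_probe, out_tx, out_start, out_mm;
  int np = probes.size(), nt = transcripts.size();
  std::vector<std::string> txs(nt);
  int min_plen = 1 << 30;
  for (int t = 0; t < nt; ++t) txs[t] = as<std::string>(transcripts[t]);
  std::vector<std::string> prs(np);
  for (int p = 0; p < np; ++p) {
    prs[p] = as<std::string>(probes[p]);
    if ((int)prs[p].size() < min_plen) min_plen = (int)prs[p].size();
  }
  int w = min_plen / (max_mm + 1);
  if (w > 32) w = 32;
  bool seeded = np > 0 && w >= 8;

  // verify one candidate alignment
  auto verify = [&](int p, int t, int s) {
    const std::string &pr = prs[p];
    const std::string &tx = txs[t];
    int plen = pr.size();
    if (s < 0 || s + plen > (int)tx.size()) return;
    int mm = 0;
    for (int j = 0; j < plen; ++j) {
      if (pr[j] != tx[s + j] && ++mm > max_mm) return;
    }
    out_probe.push_back(p + 1);
    out_tx.push_back(t + 1);
    out_start.push_back(s);
    out_mm.push_back(mm);
  };

  if (seeded) {
    // index every w-mer of every transcript as a 2-bit packed key
    std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
    uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    for (int t = 0; t < nt; ++t) {
      const std::string &tx = txs[t];
      int n = tx.size();
      uint64_t key = 0;
      int valid = 0;
      for (int i = 0; i < n; ++i) {
        int b = base2bits(tx[i]);
        if (b < 0) { valid = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++valid >= w) index[key].emplace_back(t, i - w + 1);
      }
    }
    for (int p = 0; p < np; ++p) {
      const std::string &pr = prs[p];
      int plen = pr.size();
      std::unordered_set<uint64_t> seen;
      for (int seg = 0; seg <= max_mm; ++seg) {
        int off = seg * (plen / (max_mm + 1));
        if (off + w > plen) off = plen - w;
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < w; ++j) {
          int b = base2bits(pr[off + j]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = index.find(key & mask);
        if (it == index.end()) continue;
        for (auto &cand : it->second) {
          int s = cand.second - off;
          uint64_t id = ((uint64_t)cand.first << 32) ^ (uint64_t)(s + 64);
          if (seen.insert(id).second) verify(p, cand.first, s);
        }
      }
      // candidates arrive per seed segment; restore (tx, start) order
    }
    // sort output by probe, transcript, start for a stable contract
    int nh = out_probe.size();
    std::vector<int> ord(nh);
    for (int i = 0; i < nh; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (out_probe[a] != out_probe[b]) return out_probe[a] < out_probe[b];
      if (out_tx[a] != out_tx[b]) return out_tx[a] < out_tx[b];
      return out_start[a] < out_start[b];
    });
    IntegerVector rp(nh), rt(nh), rs(nh), rm(nh);
    for (int i = 0; i < nh; ++i) {
      rp[i] = out_probe[ord[i]]; rt[i] = out_tx[ord[i]];
      rs[i] = out_start[ord[i]]; rm[i] = out_mm[ord[i]];
    }
    return DataFrame::create(_["probe_idx"] = rp, _["tx_idx"] = rt,
                             _["start"] = rs, _["mismatches"] = rm);
  }

  for (int p = 0; p < np; ++p) {
    int plen = prs[p].size();
    for (int t = 0; t < nt; ++t) {
      int tlen = txs[t].size();
      for (int s = 0; s + plen <= tlen; ++s) verify(p, t, s);
    }
  }
  return DataFrame::create(_["probe_idx"] = out_probe, _["tx_idx"] = out_tx,
                           _["start"] = out_start, _["mismatches"] = out_mm);
}

// Position-weighted adapter trimming. A mismatch at offset j of an aligned
// region of length l costs (l - j)/l, so errors near the read 3' end are
// cheap. The leftmost start with total cost <= max_cost wins; otherwise the
// read is truncated to max_tag.
// [[Rcpp::export]]
CharacterVector cpp_trim_adapter(CharacterVector reads, std::string adapter,
                                 double max_cost, int max_tag, int min_overlap) {
  int n = reads.size();
  int alen = adapter.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int rlen = rd.size();
    int cut = -1;
    for (int s = 0; s + min_overlap <= rlen; ++s) {
      int l = std::min(rlen - s, alen);
      if (l < min_overlap) break;
      double cost = 0.0;
      bool ok = true;
      for (int j = 0; j < l; ++j) {
        if (rd[s + j] != adapter[j]) {
          cost += (double)(l - j) / (double)l;
          if (cost > max_cost) { ok = false; break; }
        }
      }
      if (ok) { cut = s; break; }
    }
    if (cut < 0) cut = rlen;
    if (cut > max_tag) cut = max_tag;
    out[i] = rd.substr(0, cut);
  }
  return out;
}

// Tag counting against DpnII windows, anchored at GATC occurrences inside
// each window. A tag of length t is compared from each anchor over
// m = min(t, bases available) >= min_len bases; the minimal mismatch count
// <= max_mm wins; ties prefer longer m, then 3'-most site. Tags whose best
// matches span >= 2 gene symbols are ambiguous.
// status: 0 = unambiguous, 1 = ambiguous, 2 = no match.
// [[Rcpp::export]]
List cpp_match_tags(CharacterVector tags, CharacterVector windows,
                    List anchors, IntegerVector window_gene,
                    IntegerVector site_start, LogicalVector is3p,
                    int max_mm, int min_len) {
  int ntag = tags.size(), nw = windows.size();
  std::vector<std::string> ws(nw);
  for (int w = 0; w < nw; ++w) ws[w] = as<std::string>(windows[w]);
  // flatten (window, anchor) pairs
  std::vector<int> a_win, a_pos, a_avail;
  for (int w = 0; w < nw; ++w) {
    std::vector<int> av = as<std::vector<int>>(anchors[w]);
    for (int s : av) {
      a_win.push_back(w);
      a_pos.push_back(s);
      a_avail.push_back((int)ws[w].size() - s);
    }
  }
  int na = a_win.size();
  // pigeonhole buckets over the three 4-mers at anchor offsets 4/8/12
  // (past the shared GATC); only valid when >= 16 bases are compared, i.e.
  // tag length and availability both >= 16 — with <= 2 mismatches at least
  // one of the three 4-mers is exact. Shorter anchors are always scanned.
  auto pack4 = [](const char *s) {
    int k = 0;
    for (int j = 0; j < 4; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) return -1;
      k = (k << 2) | b;
    }
    return k;
  };
  std::vector<std::vector<int>> bucket[3];
  std::vector<int> short_anchors;
  for (int seg = 0; seg < 3; ++seg) bucket[seg].assign(256, {});
  bool use_index = na >= 64;
  if (use_index) {
    for (int a = 0; a < na; ++a) {
      if (a_avail[a] < 16) { short_anchors.push_back(a); continue; }
      const char *s = ws[a_win[a]].c_str() + a_pos[a];
      bool ok = true;
      for (int seg = 0; seg < 3; ++seg) {
        int k = pack4(s + 4 + 4 * seg);
        if (k < 0) { ok = false; break; }
        bucket[seg][k].push_back(a);
      }
      if (!ok) short_anchors.push_back(a);  // scan windows with odd bases
    }
  }
  std::vector<int> stamp(na, -1);
  std::vector<int> cand;
  IntegerVector status(ntag), best_mm_out(ntag), win_out(ntag);
  for (int i = 0; i < ntag; ++i) {
    std::string tg = as<std::string>(tags[i]);
    int t = tg.size();
    if (t < min_len) { status[i] = 2; best_mm_out[i] = NA_INTEGER; win_out[i] = NA_INTEGER; continue; }
    // candidate anchors for this tag
    cand.clear();
    bool full_scan = !use_index || t < 16;
    if (!full_scan) {
      int keys[3];
      for (int seg = 0; seg < 3 && !full_scan; ++seg) {
        keys[seg] = pack4(tg.c_str() + 4 + 4 * seg);
        if (keys[seg] < 0) full_scan = true;
      }
      if (!full_scan) {
        for (int seg = 0; seg < 3; ++seg) {
          for (int a : bucket[seg][keys[seg]]) {
            if (stamp[a] != i) { stamp[a] = i; cand.push_back(a); }
          }
        }
        for (int a : short_anchors) {
          if (stamp[a] != i) { stamp[a] = i; cand.push_back(a); }
        }
      }
    }
    if (full_scan) {
      cand.resize(na);
      for (int a = 0; a < na; ++a) cand[a] = a;
    }
    int best_mm = max_mm + 1;
    std::vector<int> cw, cm;  // candidate window idx, aligned length
    for (int a : cand) {
      const std::string &win = ws[a_win[a]];
      int s = a_pos[a];
      int m = std::min(t, a_avail[a]);
      if (m < min_len) continue;
      int mm = 0;
      bool bail = false;
      for (int j = 0; j < m; ++j) {
        if (tg[j] != win[s + j] && ++mm > best_mm) { bail = true; break; }
      }
      if (bail || mm > max_mm || mm > best_mm) continue;
      if (mm < best_mm) { best_mm = mm; cw.clear(); cm.clear(); }
      cw.push_back(a_win[a]); cm.push_back(m);
    }
    if (best_mm > max_mm) { status[i] = 2; best_mm_out[i] = NA_INTEGER; win_out[i] = NA_INTEGER; continue; }
    int g0 = window_gene[cw[0]];
    bool ambig = false;
    for (size_t k = 1; k < cw.size(); ++k)
      if (window_gene[cw[k]] != g0) { ambig = true; break; }
    if (ambig) { status[i] = 1; best_mm_out[i] = best_mm; win_out[i] = NA_INTEGER; continue; }
    int pick = 0;
    for (size_t k = 1; k < cw.size(); ++k) {
      bool better = false;
      if (cm[k] > cm[pick]) better = true;
      else if (cm[k] == cm[pick]) {
        if (is3p[cw[k]] && !is3p[cw[pick]]) better = true;
        else if (is3p[cw[k]] == is3p[cw[pick]] &&
                 site_start[cw[k]] > site_start[cw[pick]]) better = true;
      }
      if (better) pick = (int)k;
    }
    status[i] = 0; best_mm_out[i] = best_mm; win_out[i] = cw[pick] + 1;
  }
  return List::create(_["status"] = status, _["mismatches"] = best_mm_out,
                      _["window_idx"] = win_out);
}

// Apply pre-drawn substitution errors: error e mutates reads[idx[e]] at
// 1-based position pos[e]; pick in 1..3 selects among the three bases other
// than the original (alphabetical order).
// [[Rcpp::export]]
CharacterVector cpp_apply_errors(CharacterVector reads, IntegerVector idx,
                                 IntegerVector pos, IntegerVector pick) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int ne = idx.size();
  std::unordered_map<int, std::string> touched;
  for (int e = 0; e < ne; ++e) {
    int i = idx[e] - 1;
    auto it = touched.find(i);
    if (it == touched.end()) {
      it = touched.emplace(i, as<std::string>(reads[i])).first;
    }
    std::string &s = it->second;
    char orig = s[pos[e] - 1];
    int k = 0;
    for (int b = 0; b < 4; ++b) {
      if (bases[b] == orig) continue;
      if (++k == pick[e]) { s[pos[e] - 1] = bases[b]; break; }
    }
  }
  for (auto &kv : touched) reads[kv.first] = kv.second;
  return reads;
}
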