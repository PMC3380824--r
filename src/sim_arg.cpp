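// Discretised ancestral-recombination-graph simulator for the two-population
// isolation-with-migration model (mutation-scaled rates; see R/coalsim.R for
// the model description). Fast path for sample sizes up to 64 haplotypes:
// each lineage stores one 64-bit tip mask per non-recombining block.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Lineage {
  int deme;           // 1, 2, or 0 (ancestral)
  double birth;
  std::vector<uint64_t> blocks;  // tip mask per block; 0 = not carried
  int lo, hi;         // first/last carried block index, -1 if none

  void refresh_bounds() {
    lo = -1; hi = -1;
    for (int b = 0; b < (int)blocks.size(); ++b) {
      if (blocks[b]) { if (lo < 0) lo = b; hi = b; }
    }
  }
  double span(const std::vector<double>& pos) const {
    return (lo >= 0 && hi > lo) ? pos[hi] - pos[lo] : 0.0;
  }
  int carried_count() const {
    int c = 0;
    for (uint64_t m : blocks) if (m) ++c;
    return c;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_arg_cpp")]]
List sim_arg_cpp(int n1, int n2, double theta1, double theta2, double thetaA,
                 double t_split, double m1, double m2, double rho, int B,
                 double pulse_frac, double pulse_time, int pulse_founders) {
  const int n = n1 + n2;
  if (n > 64) stop("compiled ARG path supports at most 64 haplotypes");
  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);

  std::vector<double> pos(B);
  for (int b = 0; b < B; ++b) pos[b] = (b + 0.5) / B;

  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    lin[i].deme = (i < n1) ? 1 : 2;
    lin[i].birth = 0.0;
    lin[i].blocks.assign(B, 1ULL << i);
    lin[i].lo = 0; lin[i].hi = B - 1;
  }

  std::vector<uint64_t> mut_mask;
  std::vector<int> mut_block;

  auto add_mutations = [&](const Lineage& L, double t_now) {
    double dur = t_now - L.birth;
    if (dur <= 0.0) return;
    int nc = L.carried_count();
    if (nc == 0) return;
    int nm = (int)R::rpois(dur * nc / B);
    if (nm == 0) return;
    // collect carried block indices once
    std::vector<int> carried;
    carried.reserve(nc);
    for (int b = 0; b < B; ++b) if (L.blocks[b]) carried.push_back(b);
    for (int k = 0; k < nm; ++k) {
      int b = carried[(int)(R::unif_rand() * carried.size())];
      mut_mask.push_back(L.blocks[b]);
      mut_block.push_back(b);
    }
  };

  double t = 0.0;
  bool merged = (t_split <= 0.0);
  bool pulsed = (pulse_frac <= 0.0);
  if (merged) for (auto& L : lin) L.deme = 0;
  std::vector<int> pulse_tip_blocks(n, 0);  // blocks inherited via the pulse

  while (lin.size() > 1) {
    double span_sum = 0.0;
    for (const auto& L : lin) span_sum += L.span(pos);
    double rate_rec = rho * span_sum;
    int ev;  // 1,2 coal deme; 3,4 migration; 5 recombination; 6 coal ancestral
    if (!merged) {
      int k1 = 0, k2 = 0;
      for (const auto& L : lin) (L.deme == 1 ? k1 : k2)++;
      double rc1 = (double)k1 * (k1 - 1) / theta1;
      double rc2 = (double)k2 * (k2 - 1) / theta2;
      double rm1 = k1 * m1, rm2 = k2 * m2;
      double total = rc1 + rc2 + rm1 + rm2 + rate_rec;
      double boundary = (!pulsed && t < pulse_time) ? pulse_time : t_split;
      double dt = (total <= 0.0) ? R_PosInf : R::exp_rand() / total;
      if (t + dt >= boundary) {
        t = boundary;
        if (!pulsed && boundary == pulse_time) {
          // mark pulsed lineages, then collapse them into the founder set
          // (sweep ancestry: the introgressed class descends from
          // pulse_founders donor haplotypes)
          std::vector<int> sel;
          for (int i = 0; i < (int)lin.size(); ++i)
            if (lin[i].deme == 2 && R::unif_rand() < pulse_frac)
              sel.push_back(i);
          while ((int)sel.size() > pulse_founders) {
            int a = sel[sel.size() - 2], b = sel[sel.size() - 1];
            add_mutations(lin[a], t);
            add_mutations(lin[b], t);
            Lineage m_lin;
            m_lin.deme = 2;
            m_lin.birth = t;
            m_lin.blocks.assign(B, 0ULL);
            bool alive = false;
            for (int bb = 0; bb < B; ++bb) {
              uint64_t m = lin[a].blocks[bb] | lin[b].blocks[bb];
              if (m == full) m = 0ULL;
              m_lin.blocks[bb] = m;
              if (m) alive = true;
            }
            // remove b then a (b > a by construction of sel)
            lin.erase(lin.begin() + b);
            lin.erase(lin.begin() + a);
            sel.pop_back();
            sel.pop_back();
            if (alive) {
              m_lin.refresh_bounds();
              lin.push_back(m_lin);
              sel.push_back((int)lin.size() - 1);
            }
          }
          for (int i : sel) {
            lin[i].deme = 1;
            for (int bb = 0; bb < B; ++bb) {
              uint64_t m = lin[i].blocks[bb];
              for (int tp = 0; tp < n; ++tp)
                if ((m >> tp) & 1ULL) pulse_tip_blocks[tp]++;
            }
          }
          pulsed = true;
        } else {
          merged = true;
          for (auto& L : lin) L.deme = 0;
        }
        continue;
      }
      t += dt;
      double u = R::unif_rand() * total;
      if (u < rc1) ev = 1;
      else if (u < rc1 + rc2) ev = 2;
      else if (u < rc1 + rc2 + rm1) ev = 3;
      else if (u < rc1 + rc2 + rm1 + rm2) ev = 4;
      else ev = 5;
    } else {
      double k = (double)lin.size();
      double rc = k * (k - 1) / thetaA;
      double total = rc + rate_rec;
      t += R::exp_rand() / total;
      ev = (R::unif_rand() * total < rc) ? 6 : 5;
    }

    if (ev == 1 || ev == 2 || ev == 6) {
      int d = (ev == 6) ? 0 : ev;
      // pick two distinct lineages in deme d
      std::vector<int> cand;
      for (int i = 0; i < (int)lin.size(); ++i)
        if (lin[i].deme == d) cand.push_back(i);
      int ia = (int)(R::unif_rand() * cand.size());
      int ib = (int)(R::unif_rand() * (cand.size() - 1));
      if (ib >= ia) ++ib;
      int a = cand[ia], b = cand[ib];
      add_mutations(lin[a], t);
      add_mutations(lin[b], t);
      Lineage merged_lin;
      merged_lin.deme = d;
      merged_lin.birth = t;
      merged_lin.blocks.assign(B, 0ULL);
      bool alive = false;
      for (int bb = 0; bb < B; ++bb) {
        uint64_t m = lin[a].blocks[bb] | lin[b].blocks[bb];
        if (m == full) m = 0ULL;  // block found its MRCA
        merged_lin.blocks[bb] = m;
        if (m) alive = true;
      }
      if (a < b) std::swap(a, b);
      lin.erase(lin.begin() + a);
      lin.erase(lin.begin() + b);
      if (alive) {
        merged_lin.refresh_bounds();
        lin.push_back(merged_lin);
      }
    } else if (ev == 3 || ev == 4) {
      int d = ev - 2;
      std::vector<int> cand;
      for (int i = 0; i < (int)lin.size(); ++i)
        if (lin[i].deme == d) cand.push_back(i);
      lin[cand[(int)(R::unif_rand() * cand.size())]].deme = 3 - d;
    } else {
      // recombination: pick lineage proportional to span
      double u = R::unif_rand() * span_sum;
      int a = -1; double acc = 0.0;
      for (int i = 0; i < (int)lin.size(); ++i) {
        acc += lin[i].span(pos);
        if (u < acc) { a = i; break; }
      }
      if (a < 0) a = (int)lin.size() - 1;
      add_mutations(lin[a], t);
      Lineage& La = lin[a];
      double bp = pos[La.lo] + R::unif_rand() * (pos[La.hi] - pos[La.lo]);
      Lineage right;
      right.deme = La.deme;
      right.birth = t;
      right.blocks.assign(B, 0ULL);
      for (int bb = 0; bb < B; ++bb) {
        if (pos[bb] > bp) { right.blocks[bb] = La.blocks[bb]; La.blocks[bb] = 0ULL; }
      }
      La.birth = t;
      La.refresh_bounds();
      right.refresh_bounds();
      lin.push_back(right);
    }
  }

  IntegerVector ptips(pulse_tip_blocks.begin(), pulse_tip_blocks.end());
  int S = (int)mut_mask.size();
  if (S == 0) return List::create(_["X"] = R_NilValue, _["block"] = R_NilValue,
                                  _["pulse_tips"] = ptips);
  IntegerMatrix X(n, S);
  IntegerVector blockv(S);
  for (int j = 0; j < S; ++j) {
    uint64_t m = mut_mask[j];
    for (int i = 0; i < n; ++i) X(i, j) = (m >> i) & 1ULL ? 1 : 0;
    blockv[j] = mut_block[j] + 1;  // 1-based block index
  }
  return List::create(_["X"] = X, _["block"] = blockv,
                      _["pulse_tips"] = ptips);
}
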