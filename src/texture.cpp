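#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-window GLCM descriptor maps. `g` is the rebinned gray image
// replicate-padded by `half` on every border; outputs have the unpadded
// size. For every pixel the co-occurrence matrix of its w x w window at
// displacement (dr, dc) is summarized without materializing the L x L
// matrix: the normalized GLCM is the uniform distribution (with
// multiplicity) over the window's level pairs, so all four descriptors are
// pair statistics. `zero_var_flag` is set when any window has zero marginal
// variance (correlation undefined there, reported as 0).
// [[Rcpp::export]]
List glcm_maps_cpp(IntegerMatrix g, int w, int dr, int dc) {
  int half = (w - 1) / 2;
  int H = g.nrow() - 2 * half, W = g.ncol() - 2 * half;
  NumericMatrix contrast(H, W), correlation(H, W), energy(H, W),
      homogeneity(H, W);
  bool zero_var = false;

  int adr = std::abs(dr), adc = std::abs(dc);
  int nprow = w - adr, npcol = w - adc;       // pairs per window
  int npairs = (nprow > 0 && npcol > 0) ? nprow * npcol : 0;
  std::vector<double> codes;
  codes.reserve(npairs > 0 ? npairs : 1);

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (npairs == 0) continue;  // degenerate offset: all descriptors 0
      double si = 0, sj = 0, sii = 0, sjj = 0, sij = 0, con = 0, hom = 0;
      codes.clear();
      int r0 = r, c0 = c;  // window top-left in padded coords
      int rlo = (dr >= 0) ? 0 : adr, clo = (dc >= 0) ? 0 : adc;
      for (int a = 0; a < nprow; ++a) {
        for (int b = 0; b < npcol; ++b) {
          int i = g(r0 + rlo + a, c0 + clo + b);
          int j = g(r0 + rlo + a + dr, c0 + clo + b + dc);
          double d = (double)i - (double)j;
          si += i; sj += j; sii += (double)i * i; sjj += (double)j * j;
          sij += (double)i * j;
          con += d * d;
          hom += 1.0 / (1.0 + std::fabs(d));
          codes.push_back((double)i * 1048576.0 + (double)j);
        }
      }
      double T = npairs;
      contrast(r, c) = con / T;
      homogeneity(r, c) = hom / T;
      std::sort(codes.begin(), codes.end());
      double en = 0;
      for (size_t k = 0; k < codes.size();) {
        size_t k2 = k;
        while (k2 < codes.size() && codes[k2] == codes[k]) ++k2;
        double p = (double)(k2 - k) / T;
        en += p * p;
        k = k2;
      }
      energy(r, c) = en;
      double mi = si / T, mj = sj / T;
      double vi = sii / T - mi * mi, vj = sjj / T - mj * mj;
      if (vi <= 0 || vj <= 0) {
        zero_var = true;
        correlation(r, c) = 0.0;
      } else {
        correlation(r, c) = (sij / T - mi * mj) / std::sqrt(vi * vj);
      }
    }
  }
  return List::create(_["contrast"] = contrast,
                      _["correlation"] = correlation,
                      _["energy"] = energy,
                      _["homogeneity"] = homogeneity,
                      _["zero_variance_seen"] = zero_var);
}

// Sliding-window Shannon entropy (bits) of the gray-level histogram.
// `g` is replicate-padded by (w-1)/2; output has the unpadded size.
// [[Rcpp::export]]
NumericMatrix entropy_map_cpp(IntegerMatrix g, int w) {
  int half = (w - 1) / 2;
  int H = g.nrow() - 2 * half, W = g.ncol() - 2 * half;
  NumericMatrix out(H, W);
  int npix = w * w;
  std::vector<int> vals(npix);
  const double log2e = 1.0 / std::log(2.0);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int k = 0;
      for (int a = 0; a < w; ++a)
        for (int b = 0; b < w; ++b) vals[k++] = g(r + a, c + b);
      std::sort(vals.begin(), vals.end());
      double ent = 0;
      for (int i = 0; i < npix;) {
        int i2 = i;
        while (i2 < npix && vals[i2] == vals[i]) ++i2;
        double p = (double)(i2 - i) / npix;
        ent -= p * std::log(p) * log2e;
        i = i2;
      }
      out(r, c) = ent;
    }
  }
  return out;
}

// 8-connected component labeling of a binary mask (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // scan is column-major; already-visited 8-neighbours are
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int nbr_r[4] = {r - 1, r - 1, r, r + 1};
      int nbr_c[4] = {c, c - 1, c - 1, c - 1};
      for (int k = 0; k < 4; ++k) {
        int rr = nbr_r[k], cc = nbr_c[k];
        if (rr < 0 || rr >= H || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
      }
    }
  }
  // resolve and compact labels
  std::vector<int> remap(next, 0);
  int out_n = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++out_n;
        lab(r, c) = remap[root];
      }
  return lab;
}
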