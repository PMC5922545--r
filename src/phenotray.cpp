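#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by flood fill.
// Returns an integer matrix with labels 1..K (0 = background).
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        lab(r, c) = next;
        stack.clear();
        stack.push_back(r + c * H);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int rr = idx % H, cc = idx / H;
          for (int k = 0; k < nd; ++k) {
            int r2 = rr + dr[k], c2 = cc + dc[k];
            if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W &&
                mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// SLIC superpixel over-segmentation in CIE L*a*b*.
// L, A, B: H x W channel matrices. Returns list(labels, n) where labels is a
// 1-based H x W integer matrix with contiguous ids 1..n. The distance is
// d_lab^2 + (d_xy / S)^2 * m^2 with grid step S = sqrt(H*W/n_target) and
// compactness m. Connectivity is enforced afterwards by merging fragments
// smaller than S^2/4 into an adjacent superpixel.
// [[Rcpp::export(name = ".slic_superpixels")]]
List slic_superpixels(const NumericMatrix& L, const NumericMatrix& A,
                      const NumericMatrix& B, int n_target,
                      double compactness, int max_iter = 10) {
  const int H = L.nrow(), W = L.ncol();
  const double S = std::sqrt((double)H * (double)W / (double)n_target);
  const double invS2m2 = (compactness * compactness) / (S * S);

  // centers seeded on a regular grid at spacing S
  std::vector<double> cl, ca, cb, cx, cy;
  for (double y = S / 2.0; y < H; y += S) {
    for (double x = S / 2.0; x < W; x += S) {
      int r = (int)y, c = (int)x;
      cl.push_back(L(r, c));
      ca.push_back(A(r, c));
      cb.push_back(B(r, c));
      cx.push_back(x);
      cy.push_back(y);
    }
  }
  int K = (int)cl.size();
  if (K < 1) {
    cl.assign(1, L(H / 2, W / 2));
    ca.assign(1, A(H / 2, W / 2));
    cb.assign(1, B(H / 2, W / 2));
    cx.assign(1, W / 2.0);
    cy.assign(1, H / 2.0);
    K = 1;
  }

  std::vector<int> lab(H * W, 0);
  std::vector<double> dist(H * W);
  const int win = (int)std::ceil(S);

  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int r0 = std::max(0, (int)(cy[k] - win));
      int r1 = std::min(H - 1, (int)(cy[k] + win));
      int c0 = std::max(0, (int)(cx[k] - win));
      int c1 = std::min(W - 1, (int)(cx[k] + win));
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          double dl = L(r, c) - cl[k];
          double da = A(r, c) - ca[k];
          double db = B(r, c) - cb[k];
          double dx = (c + 0.5) - (cx[k] + 0.5);
          double dy = (r + 0.5) - (cy[k] + 0.5);
          double d = dl * dl + da * da + db * db +
                     (dx * dx + dy * dy) * invS2m2;
          int idx = r + c * H;
          if (d < dist[idx]) {
            dist[idx] = d;
            lab[idx] = k;
          }
        }
      }
    }
    // update centers
    std::vector<double> sl(K, 0), sa(K, 0), sb(K, 0), sx(K, 0), sy(K, 0);
    std::vector<int> cnt(K, 0);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int k = lab[r + c * H];
        sl[k] += L(r, c);
        sa[k] += A(r, c);
        sb[k] += B(r, c);
        sx[k] += c;
        sy[k] += r;
        cnt[k]++;
      }
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] > 0) {
        cl[k] = sl[k] / cnt[k];
        ca[k] = sa[k] / cnt[k];
        cb[k] = sb[k] / cnt[k];
        cx[k] = sx[k] / cnt[k];
        cy[k] = sy[k] / cnt[k];
      }
    }
  }

  // enforce connectivity: flood fill in scan order; fragments below min_size
  // are absorbed by the adjacent superpixel encountered first.
  const int min_size = std::max(1, (int)(S * S / 4.0));
  std::vector<int> newlab(H * W, -1);
  std::vector<int> region;
  region.reserve(4096);
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  int nl = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int idx = r + c * H;
      if (newlab[idx] >= 0) continue;
      int old = lab[idx];
      // neighbor label already assigned (for possible merge)
      int adj = -1;
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr4[k], c2 = c + dc4[k];
        if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W &&
            newlab[r2 + c2 * H] >= 0) {
          adj = newlab[r2 + c2 * H];
          break;
        }
      }
      region.clear();
      region.push_back(idx);
      newlab[idx] = nl;
      size_t head = 0;
      while (head < region.size()) {
        int i2 = region[head++];
        int rr = i2 % H, cc = i2 / H;
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr4[k], c2 = cc + dc4[k];
          if (r2 >= 0 && r2 < H && c2 >= 0 && c2 < W) {
            int j = r2 + c2 * H;
            if (newlab[j] < 0 && lab[j] == old) {
              newlab[j] = nl;
              region.push_back(j);
            }
          }
        }
      }
      if ((int)region.size() < min_size && adj >= 0) {
        for (size_t i = 0; i < region.size(); ++i) newlab[region[i]] = adj;
      } else {
        ++nl;
      }
    }
  }

  IntegerMatrix out(H, W);
  for (int i = 0; i < H * W; ++i) out[i] = newlab[i] + 1;
  return List::create(_["labels"] = out, _["n"] = nl);
}

// Projective warp by inverse mapping with bilinear interpolation.
// img: H x W x C numeric array (values arbitrary scale); hinv maps output
// coordinates to source coordinates. Coordinates are continuous, 0-based,
// x rightward / y downward, with pixel (r, c) (1-based) centered at
// (c - 0.5, r - 0.5). Points outside the source extent get `fill`.
// [[Rcpp::export(name = ".warp_projective")]]
NumericVector warp_projective(const NumericVector& img,
                              const NumericMatrix& hinv, int out_h, int out_w,
                              const NumericVector& fill) {
  IntegerVector dims = img.attr("dim");
  const int H = dims[0], W = dims[1], C = (dims.size() > 2) ? dims[2] : 1;
  NumericVector out(out_h * out_w * C);
  out.attr("dim") = (C > 1)
                        ? IntegerVector::create(out_h, out_w, C)
                        : IntegerVector::create(out_h, out_w, 1);
  const double h11 = hinv(0, 0), h12 = hinv(0, 1), h13 = hinv(0, 2);
  const double h21 = hinv(1, 0), h22 = hinv(1, 1), h23 = hinv(1, 2);
  const double h31 = hinv(2, 0), h32 = hinv(2, 1), h33 = hinv(2, 2);
  for (int c = 0; c < out_w; ++c) {
    double x = c + 0.5;
    for (int r = 0; r < out_h; ++r) {
      double y = r + 0.5;
      double wz = h31 * x + h32 * y + h33;
      double sx = (h11 * x + h12 * y + h13) / wz;
      double sy = (h21 * x + h22 * y + h23) / wz;
      int o = r + c * out_h;
      if (sx < 0 || sx > W || sy < 0 || sy > H || wz == 0 ||
          !std::isfinite(sx) || !std::isfinite(sy)) {
        for (int ch = 0; ch < C; ++ch)
          out[o + ch * out_h * out_w] = fill[ch % fill.size()];
        continue;
      }
      // fractional 1-based pixel-center coordinates
      double colf = sx + 0.5, rowf = sy + 0.5;
      int c0 = (int)std::floor(colf), r0 = (int)std::floor(rowf);
      double fc = colf - c0, fr = rowf - r0;
      int c1 = c0 + 1, r1 = r0 + 1;
      if (c0 < 1) { c0 = 1; }
      if (r0 < 1) { r0 = 1; }
      if (c1 > W) { c1 = W; }
      if (r1 > H) { r1 = H; }
      if (c0 > W) c0 = W;
      if (r0 > H) r0 = H;
      for (int ch = 0; ch < C; ++ch) {
        const double* p = &img[ch * H * W];
        double v00 = p[(r0 - 1) + (c0 - 1) * H];
        double v01 = p[(r0 - 1) + (c1 - 1) * H];
        double v10 = p[(r1 - 1) + (c0 - 1) * H];
        double v11 = p[(r1 - 1) + (c1 - 1) * H];
        out[o + ch * out_h * out_w] = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                                      fr * ((1 - fc) * v10 + fc * v11);
      }
    }
  }
  return out;
}
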