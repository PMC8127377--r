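// Collaborative-filter core: correlation-compensated block matching, joint
// 3-D transform (2-D orthonormal transform per block + 1-D Haar across the
// stack), exact per-coefficient noise variances evaluated from
// cross-covariance lookup tables, hard-threshold / Wiener shrinkage, and
// adaptive weighted aggregation.
//
// Conventions shared with the R side:
//  * 2-D coefficients are flattened column-major over the bs x bs grid,
//  * luts has dimensions (nr, nc, N): element (dr, dc, i) is the covariance
//    of 2-D coefficient i between two blocks at circular offset (dr, dc),
//  * plut(dr, dc) is the total transform-domain variance of the difference
//    of two blocks at that offset (the matching penalty).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Cand {
  double dist;
  int r, c;
  bool operator<(const Cand& o) const { return dist < o.dist; }
};

int pow2_floor(int n) {
  int p = 1;
  while (2 * p <= n) p *= 2;
  return p;
}

// candidates within the search window, ranked by penalized distance
void match_one(const NumericMatrix& src, int rr, int rc, int bs, int srad,
               int Mmax, double gamma, const NumericMatrix& plut,
               std::vector<Cand>& group) {
  const int nr = src.nrow(), nc = src.ncol();
  const int r0 = std::max(0, rr - srad), r1 = std::min(nr - bs, rr + srad);
  const int c0 = std::max(0, rc - srad), c1 = std::min(nc - bs, rc + srad);
  std::vector<Cand> cand;
  cand.reserve((r1 - r0 + 1) * (c1 - c0 + 1));
  for (int c = c0; c <= c1; ++c) {
    for (int r = r0; r <= r1; ++r) {
      if (r == rr && c == rc) continue;
      double d = 0.0;
      for (int q = 0; q < bs; ++q) {
        const double* a = &src(rr, rc + q);
        const double* b = &src(r, c + q);
        for (int p = 0; p < bs; ++p) {
          const double diff = a[p] - b[p];
          d += diff * diff;
        }
      }
      if (gamma != 0.0) {
        const int dr = ((r - rr) % nr + nr) % nr;
        const int dc = ((c - rc) % nc + nc) % nc;
        d -= gamma * plut(dr, dc);
      }
      cand.push_back({d, r, c});
    }
  }
  const int M = std::min(Mmax, pow2_floor((int)cand.size() + 1));
  group.clear();
  group.push_back({0.0, rr, rc});
  if (M > 1) {
    std::partial_sort(cand.begin(), cand.begin() + (M - 1), cand.end());
    for (int k = 0; k < M - 1; ++k) group.push_back(cand[k]);
  }
  std::sort(group.begin(), group.end());
}

// sparse Haar supports: for each basis j the (index, value) pairs of its
// row, and for each stack position m those of its column (the Haar matrix
// has only ~log2(M) nonzeros per column, which makes the inverse transform
// and the variance quadratic forms cheap).
struct HaarSparse {
  std::vector<std::vector<std::pair<int, double>>> rows, cols;
};

HaarSparse sparsify(const NumericMatrix& H) {
  HaarSparse s;
  s.rows.resize(H.nrow());
  s.cols.resize(H.ncol());
  for (int j = 0; j < H.nrow(); ++j)
    for (int m = 0; m < H.ncol(); ++m)
      if (std::abs(H(j, m)) > 1e-14) {
        s.rows[j].push_back({m, H(j, m)});
        s.cols[m].push_back({j, H(j, m)});
      }
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_match_blocks(NumericMatrix image, int rr, int rc, int bs, int srad,
                      int Mmax, double gamma, NumericMatrix plut) {
  std::vector<Cand> group;
  match_one(image, rr, rc, bs, srad, Mmax, gamma, plut, group);
  const int M = (int)group.size();
  IntegerMatrix pos(M, 2);
  NumericVector dist(M);
  for (int m = 0; m < M; ++m) {
    pos(m, 0) = group[m].r;
    pos(m, 1) = group[m].c;
    dist[m] = group[m].dist;
  }
  return List::create(_["positions"] = pos, _["distances"] = dist);
}

// [[Rcpp::export]]
NumericMatrix cpp_bm3d_stage(NumericMatrix z, NumericMatrix match_src,
                             NumericMatrix pilot, NumericVector luts,
                             NumericMatrix plut, NumericMatrix t2d,
                             List haars, int step, int srad, int Mmax,
                             double gamma, double lambda, double mu2,
                             bool wiener) {
  const int nr = z.nrow(), nc = z.ncol();
  const int bs = t2d.nrow();
  const int N = bs * bs;
  const int nrc = nr * nc;
  const double* lut = luts.begin();

  // sparse Haar supports per power-of-two size
  std::map<int, HaarSparse> hsp;
  for (int i = 0; i < haars.size(); ++i) {
    NumericMatrix H = haars[i];
    hsp.emplace(H.nrow(), sparsify(H));
  }

  // reference grid, clamped so the last block abuts the border
  std::vector<int> rgrid, cgrid;
  for (int r = 0; r <= nr - bs; r += step) rgrid.push_back(r);
  if (rgrid.back() != nr - bs) rgrid.push_back(nr - bs);
  for (int c = 0; c <= nc - bs; c += step) cgrid.push_back(c);
  if (cgrid.back() != nc - bs) cgrid.push_back(nc - bs);

  NumericMatrix num(nr, nc), den(nr, nc);
  std::vector<Cand> group;
  std::vector<double> coef(N * Mmax), th(N * Mmax), pcoef(N * Mmax),
      pth(N * Mmax), var(N * Mmax), tmp(N), est(N * Mmax);
  std::vector<int> off(Mmax * Mmax);

  auto dct2 = [&](const NumericMatrix& img, int r0, int c0, double* out) {
    // out(p + bs*q) = [D * B * D^T](p, q)
    for (int q = 0; q < bs; ++q) {   // tmp = D * B
      for (int p = 0; p < bs; ++p) {
        double s = 0.0;
        for (int u = 0; u < bs; ++u) s += t2d(p, u) * img(r0 + u, c0 + q);
        tmp[p + bs * q] = s;
      }
    }
    for (int p = 0; p < bs; ++p) {
      for (int q = 0; q < bs; ++q) {
        double s = 0.0;
        for (int v = 0; v < bs; ++v) s += tmp[p + bs * v] * t2d(q, v);
        out[p + bs * q] = s;
      }
    }
  };

  for (size_t ri = 0; ri < rgrid.size(); ++ri) {
    for (size_t ci = 0; ci < cgrid.size(); ++ci) {
      match_one(match_src, rgrid[ri], cgrid[ci], bs, srad, Mmax, gamma, plut,
                group);
      const int M = (int)group.size();
      const HaarSparse& HS = hsp.at(M);

      // 2-D transforms of the group (and of the pilot group for Wiener)
      for (int m = 0; m < M; ++m) {
        dct2(z, group[m].r, group[m].c, &coef[m * N]);
        if (wiener) dct2(pilot, group[m].r, group[m].c, &pcoef[m * N]);
      }
      // 1-D transform across the stack: th(i, j) = sum_m H(j, m) coef(i, m)
      for (int j = 0; j < M; ++j) {
        for (int i = 0; i < N; ++i) {
          double s = 0.0, sp = 0.0;
          for (auto& e : HS.rows[j]) {
            s += e.second * coef[e.first * N + i];
            if (wiener) sp += e.second * pcoef[e.first * N + i];
          }
          th[j * N + i] = s;
          if (wiener) pth[j * N + i] = sp;
        }
      }
      // exact coefficient variances from the covariance lookup tables
      for (int m = 0; m < M; ++m)
        for (int l = 0; l < M; ++l) {
          const int dr = ((group[m].r - group[l].r) % nr + nr) % nr;
          const int dc = ((group[m].c - group[l].c) % nc + nc) % nc;
          off[m * M + l] = dr + nr * dc;
        }
      for (int i = 0; i < N; ++i) {
        const double* li = lut + (size_t)i * nrc;
        for (int j = 0; j < M; ++j) {
          const auto& sup = HS.rows[j];
          const int ns = (int)sup.size();
          double v = 0.0;
          for (int a = 0; a < ns; ++a) {
            const double ha = sup[a].second;
            const int ma = sup[a].first * M;
            v += ha * ha * li[off[ma + sup[a].first]];
            double vo = 0.0;
            for (int b = a + 1; b < ns; ++b)
              vo += sup[b].second * li[off[ma + sup[b].first]];
            v += 2.0 * ha * vo;
          }
          var[j * N + i] = v > 0.0 ? v : 0.0;
        }
      }

      double wsum = 0.0;  // residual-variance total for the group weight
      if (!wiener) {
        for (int j = 0; j < M; ++j) {
          for (int i = 0; i < N; ++i) {
            const int idx = j * N + i;
            const bool keep = (i == 0 && j == 0) ||
                              std::abs(th[idx]) >= lambda * std::sqrt(var[idx]);
            if (keep) {
              wsum += var[idx];
            } else {
              th[idx] = 0.0;
            }
          }
        }
      } else {
        for (int j = 0; j < M; ++j) {
          for (int i = 0; i < N; ++i) {
            const int idx = j * N + i;
            const double p2 = pth[idx] * pth[idx];
            const double d = p2 + mu2 * var[idx];
            const double alpha = (var[idx] == 0.0) ? 1.0
                                : (d > 0.0 ? p2 / d : 0.0);
            th[idx] *= alpha;
            wsum += alpha * alpha * var[idx];
          }
        }
      }
      const double w = 1.0 / std::max(wsum, 1e-12);

      // inverse 1-D: est(i, m) = sum_j H(j, m) th(i, j), H column-sparse
      for (int m = 0; m < M; ++m) {
        double* em = &est[m * N];
        const auto& col = HS.cols[m];
        for (int i = 0; i < N; ++i) {
          double s = 0.0;
          for (auto& e : col) s += e.second * th[e.first * N + i];
          em[i] = s;
        }
      }
      // inverse 2-D and aggregation (uniform block window)
      for (int m = 0; m < M; ++m) {
        const double* c2 = &est[m * N];
        for (int q = 0; q < bs; ++q) {   // tmp = D^T * C
          for (int p = 0; p < bs; ++p) {
            double s = 0.0;
            for (int u = 0; u < bs; ++u) s += t2d(u, p) * c2[u + bs * q];
            tmp[p + bs * q] = s;
          }
        }
        const int r0 = group[m].r, c0 = group[m].c;
        for (int q = 0; q < bs; ++q) {
          for (int p = 0; p < bs; ++p) {
            double s = 0.0;
            for (int v = 0; v < bs; ++v) s += tmp[p + bs * v] * t2d(v, q);
            num(r0 + p, c0 + q) += w * s;
            den(r0 + p, c0 + q) += w;
          }
        }
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (den(r, c) == 0.0) stop("aggregation left uncovered pixels");
      out(r, c) = num(r, c) / den(r, c);
    }
  return out;
}
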