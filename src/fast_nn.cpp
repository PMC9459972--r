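#include <Rcpp.h>
using namespace Rcpp;

// Nearest row of B for each row of A under Euclidean distance; ties break
// toward the lowest index. Hot path of every ICP iteration, hence C++ with
// contiguous column-pointer access (R matrices are column-major).
// [[Rcpp::export(name = ".fs_nn")]]
List fs_nn(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  if (B.ncol() != d) stop("dimension mismatch in nearest-neighbour search");
  IntegerVector idx(n);
  NumericVector dist(n);
  const double *a = REAL(A);
  const double *b = REAL(B);
  if (d == 3) {
    const double *ax = a, *ay = a + n, *az = a + 2 * n;
    const double *bx = b, *by = b + m, *bz = b + 2 * m;
    for (int i = 0; i < n; ++i) {
      const double px = ax[i], py = ay[i], pz = az[i];
      double bestd = R_PosInf;
      int bestj = 0;
      for (int j = 0; j < m; ++j) {
        const double dx = px - bx[j], dy = py - by[j], dz = pz - bz[j];
        const double s = dx * dx + dy * dy + dz * dz;
        if (s < bestd) {
          bestd = s;
          bestj = j;
        }
      }
      idx[i] = bestj + 1;
      dist[i] = std::sqrt(bestd);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double bestd = R_PosInf;
      int bestj = 0;
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          const double diff = a[i + (R_xlen_t)k * n] - b[j + (R_xlen_t)k * m];
          s += diff * diff;
        }
        if (s < bestd) {
          bestd = s;
          bestj = j;
        }
      }
      idx[i] = bestj + 1;
      dist[i] = std::sqrt(bestd);
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}
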