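#include <Rcpp.h>
#include <cmath>

// Closed-form contribution of one ordered segment pair to the writhe:
// the signed solid angle swept by the connecting direction (the area of
// the spherical quadrilateral spanned by the four endpoint-to-endpoint
// unit vectors), divided by 4*pi.  Each unordered pair is counted once,
// so the cross-pair sum over two closed polygons is their integer
// linking number; the sign follows the right-hand-rule crossing
// convention.  The quadrilateral is split into two spherical triangles
// evaluated with the atan2-of-triple-product formula, which keeps full
// precision near coplanar geometry.

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double triple3(const double *x, const double *y,
                             const double *z) {
  return x[0] * (y[1] * z[2] - y[2] * z[1]) -
         x[1] * (y[0] * z[2] - y[2] * z[0]) +
         x[2] * (y[0] * z[1] - y[1] * z[0]);
}

// signed solid angle of the spherical triangle with unit-vector vertices
static inline double sph_tri(const double *a, const double *b,
                             const double *c) {
  return 2.0 * std::atan2(triple3(a, b, c),
                          1.0 + dot3(a, b) + dot3(b, c) + dot3(c, a));
}

// p0,p1: endpoints of the first segment; q0,q1: of the second.
// Connecting directions shorter than 1e-12 (shared endpoints) give 0.
static double seg_pair_w(const double *p0, const double *p1,
                         const double *q0, const double *q1) {
  double a[3], b[3], c[3], d[3];
  for (int k = 0; k < 3; ++k) {
    a[k] = q0[k] - p0[k];
    b[k] = q1[k] - p0[k];
    c[k] = q1[k] - p1[k];
    d[k] = q0[k] - p1[k];
  }
  const double eps = 1e-12;
  double la = std::sqrt(dot3(a, a)), lb = std::sqrt(dot3(b, b));
  double lc = std::sqrt(dot3(c, c)), ld = std::sqrt(dot3(d, d));
  if (la < eps || lb < eps || lc < eps || ld < eps) return 0.0;
  for (int k = 0; k < 3; ++k) {
    a[k] /= la; b[k] /= lb; c[k] /= lc; d[k] /= ld;
  }
  return -(sph_tri(a, b, c) + sph_tri(a, c, d)) / (4.0 * M_PI);
}

//' @noRd
// [[Rcpp::export(name = ".writhe_table_cpp")]]
Rcpp::List writhe_table_cpp(Rcpp::NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) Rcpp::stop("need at least 3 points (2 segments)");
  const int S = n - 1;

  // contiguous copy of the coordinates, row i = point i
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pts(i, 0);
    P[3 * i + 1] = pts(i, 1);
    P[3 * i + 2] = pts(i, 2);
  }

  Rcpp::NumericMatrix W(S, S);
  long long n_evals = 0;

  // inclusion-exclusion over growing sub-chain span:
  // W(a,b) = W(a,b-1) + W(a+1,b) - W(a+1,b-1) + w(a,b)
  for (int d = 1; d < S; ++d) {
    for (int a = 0; a + d < S; ++a) {
      int b = a + d;
      double w;
      if (d == 1) {
        w = 0.0; // consecutive segments share an endpoint: solid angle vanishes
      } else {
        w = seg_pair_w(&P[3 * a], &P[3 * (a + 1)], &P[3 * b], &P[3 * (b + 1)]);
      }
      ++n_evals;
      double acc = W(a, b - 1) + W(a + 1, b) + w;
      if (d >= 2) acc -= W(a + 1, b - 1);
      W(a, b) = acc;
    }
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("n_pair_evals") = (double)n_evals);
}
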