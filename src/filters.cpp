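#include <Rcpp.h>
#include <zlib.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Median of the defined (non-NA) values within the window around each
// missing pixel; one pass. Defined pixels are never touched. Returns the
// updated matrix and the number of pixels imputed in this pass.
// [[Rcpp::export]]
List impute_pass_cpp(NumericMatrix v, int window) {
  int nr = v.nrow(), nc = v.ncol();
  int k = window / 2;
  NumericMatrix out = clone(v);
  int n_imputed = 0;
  std::vector<double> buf;
  buf.reserve((size_t)window * window);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!NumericMatrix::is_na(v(r, c))) continue;
      buf.clear();
      int r0 = std::max(0, r - k), r1 = std::min(nr - 1, r + k);
      int c0 = std::max(0, c - k), c1 = std::min(nc - 1, c + k);
      for (int cc = c0; cc <= c1; ++cc)
        for (int rr = r0; rr <= r1; ++rr)
          if (!NumericMatrix::is_na(v(rr, cc))) buf.push_back(v(rr, cc));
      if (buf.empty()) continue;
      size_t n = buf.size(), mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(r, c) = med;
      ++n_imputed;
    }
  }
  return List::create(_["values"] = out, _["n_imputed"] = n_imputed);
}

// Sliding-window maximum (square window, truncated at the borders).
// [[Rcpp::export]]
NumericMatrix max_filter_cpp(NumericMatrix v, int window) {
  int nr = v.nrow(), nc = v.ncol();
  int k = window / 2;
  // separable: rows first, then columns
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int r0 = std::max(0, r - k), r1 = std::min(nr - 1, r + k);
      double m = v(r0, c);
      for (int rr = r0 + 1; rr <= r1; ++rr) m = std::max(m, v(rr, c));
      tmp(r, c) = m;
    }
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int c0 = std::max(0, c - k), c1 = std::min(nc - 1, c + k);
      double m = tmp(r, c0);
      for (int cc = c0 + 1; cc <= c1; ++cc) m = std::max(m, tmp(r, cc));
      out(r, c) = m;
    }
  }
  return out;
}

// Bilinear sampling at fractional (row, col) positions (1-based, matching R
// indexing of the matrix). clamp = true replicates the border; otherwise
// out-of-bounds samples are NA.
// [[Rcpp::export]]
NumericVector bilinear_cpp(NumericMatrix v, NumericVector row,
                           NumericVector col, bool clamp) {
  int nr = v.nrow(), nc = v.ncol();
  R_xlen_t n = row.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = row[i] - 1.0, c = col[i] - 1.0;
    if (clamp) {
      r = std::min(std::max(r, 0.0), (double)(nr - 1));
      c = std::min(std::max(c, 0.0), (double)(nc - 1));
    } else if (r < 0 || r > nr - 1 || c < 0 || c > nc - 1) {
      out[i] = NA_REAL;
      continue;
    }
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
    double fr = r - r0, fc = c - c0;
    double top = v(r0, c0) * (1 - fc) + v(r0, c1) * fc;
    double bot = v(r1, c0) * (1 - fc) + v(r1, c1) * fc;
    out[i] = top * (1 - fr) + bot * fr;
  }
  return out;
}

// zlib (RFC 1950) compression of a raw vector, as needed for PNG IDAT.
// [[Rcpp::export]]
RawVector zlib_compress_cpp(RawVector data, int level) {
  uLong src_len = (uLong)data.size();
  uLong bound = compressBound(src_len);
  std::vector<Bytef> dest(bound);
  uLongf dest_len = bound;
  int rc = compress2(dest.data(), &dest_len, (const Bytef *)RAW(data),
                     src_len, level);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector out(dest_len);
  std::copy(dest.begin(), dest.begin() + dest_len, out.begin());
  return out;
}

// CRC-32 of a raw vector (PNG chunk checksum), returned as a double because
// R has no unsigned 32-bit integer type.
// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef *)RAW(data), (uInt)data.size());
  return (double)crc;
}
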