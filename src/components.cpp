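#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 26-connected component labelling of a 3D logical array.
// Returns an integer array of the same dim: 0 background, 1..k components.
// Iterative BFS with an explicit stack (recursion would overflow on large blobs).
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("n_components") = IntegerVector::create(next);
  return lab;
}

// CRC-32 (IEEE 802.3, reflected) of a raw vector; needed by the store-only
// ZIP writer used for ImageJ ROI archives.
// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  crc ^= 0xFFFFFFFFu;
  return (double)crc;  // fits exactly in a double; R has no uint32
}
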