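#include <Rcpp.h>
#include <zlib.h>
#include <cmath>

using namespace Rcpp;

// zlib-format (RFC 1950) compression, as required inside PNG IDAT chunks.
// [[Rcpp::export(name = ".zlib_deflate")]]
RawVector zlib_deflate(RawVector data, int level = 6) {
  uLong src_len = data.size();
  uLong bound = compressBound(src_len);
  std::vector<Bytef> out(bound);
  uLongf out_len = bound;
  int rc = compress2(out.data(), &out_len,
                     reinterpret_cast<const Bytef *>(RAW(data)), src_len,
                     level);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector res(out_len);
  std::copy(out.begin(), out.begin() + out_len, RAW(res));
  return res;
}

// [[Rcpp::export(name = ".crc32_bytes")]]
double crc32_bytes(RawVector data) {
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, reinterpret_cast<const Bytef *>(RAW(data)), data.size());
  return static_cast<double>(crc);
}

// Rasterize a set of capsules (bone segments with radii, meters, camera
// frame: x right, y up, z away) into a depth image. Pinhole projection
// u = cx + fx*x/z, v = cy - fy*y/z. Front-surface depth in millimeters,
// 0 = no return. Nearest surface wins (z-buffer).
// joints: n x 3 (x, y, z); bones: m x 2 1-based joint indices; radii_m: m.
// [[Rcpp::export(name = ".raster_capsules")]]
IntegerMatrix raster_capsules(NumericMatrix joints, IntegerMatrix bones,
                              NumericVector radii_m, int width, int height,
                              double fx, double fy, double cx, double cy) {
  IntegerMatrix depth(height, width);  // row-major image: [v, u]
  for (int b = 0; b < bones.nrow(); ++b) {
    int j1 = bones(b, 0) - 1, j2 = bones(b, 1) - 1;
    double ax = joints(j1, 0), ay = joints(j1, 1), az = joints(j1, 2);
    double bx = joints(j2, 0), by = joints(j2, 1), bz = joints(j2, 2);
    double r = radii_m[b];
    if (az <= 0.0 || bz <= 0.0) continue;  // behind camera: caller validates
    // project endpoints
    double ua = cx + fx * ax / az, va = cy - fy * ay / az;
    double ub = cx + fx * bx / bz, vb = cy - fy * by / bz;
    double rho_a = fx * r / az, rho_b = fx * r / bz;
    double rho_max = std::max(rho_a, rho_b);
    int u0 = std::max(0, (int)std::floor(std::min(ua, ub) - rho_max - 1));
    int u1 = std::min(width - 1, (int)std::ceil(std::max(ua, ub) + rho_max + 1));
    int v0 = std::max(0, (int)std::floor(std::min(va, vb) - rho_max - 1));
    int v1 = std::min(height - 1, (int)std::ceil(std::max(va, vb) + rho_max + 1));
    if (u0 > u1 || v0 > v1) continue;
    double dx = ub - ua, dy = vb - va;
    double seg2 = dx * dx + dy * dy;
    for (int v = v0; v <= v1; ++v) {
      for (int u = u0; u <= u1; ++u) {
        double t = 0.0;
        if (seg2 > 0.0)
          t = std::min(1.0, std::max(0.0,
              ((u - ua) * dx + (v - va) * dy) / seg2));
        double qu = ua + t * dx, qv = va + t * dy;
        double du = u - qu, dv = v - qv;
        double d = std::sqrt(du * du + dv * dv);
        double z = az + t * (bz - az);
        double rho = fx * r / z;
        if (d > rho) continue;
        double bulge = r * std::sqrt(std::max(0.0, 1.0 - (d / rho) * (d / rho)));
        int mm = (int)std::lround((z - bulge) * 1000.0);
        if (mm < 1) mm = 1;
        int cur = depth(v, u);
        if (cur == 0 || mm < cur) depth(v, u) = mm;
      }
    }
  }
  return depth;
}
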