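#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Orthographic z-buffer rasterizer.
//
// Camera model: parallel rays along -camdir (camdir is the unit vector from
// the mesh centroid toward the camera). Image right = rightv, image up = upv
// (both unit, orthogonal to camdir). Pixel centers sit at integer (row, col),
// row 1 at the top; the image center maps to the centroid. Depth stored per
// pixel is the distance from the camera plane placed depth_offset mesh units
// in front of the centroid; smaller depth = closer to the camera. Background
// pixels carry R_PosInf depth and faceid 0.
//
// Ties at shared edges resolve to the smallest face index (strict < test,
// faces visited in order).
// [[Rcpp::export]]
List cpp_render(NumericMatrix V, IntegerMatrix F,
                NumericMatrix UV, NumericVector tex, IntegerVector texdim,
                NumericVector center, NumericVector camdir,
                NumericVector rightv, NumericVector upv,
                int nrow, int ncol, double scale, double depth_offset,
                NumericVector bg) {
  const int nv = V.nrow(), nf = F.nrow();
  const bool textured = UV.nrow() == nv && texdim.size() == 2;
  const double r0 = (nrow + 1) / 2.0, c0 = (ncol + 1) / 2.0;

  std::vector<double> pc(nv), pr(nv), pd(nv);
  for (int i = 0; i < nv; ++i) {
    double x = V(i, 0) - center[0], y = V(i, 1) - center[1],
           z = V(i, 2) - center[2];
    pc[i] = c0 + scale * (x * rightv[0] + y * rightv[1] + z * rightv[2]);
    pr[i] = r0 - scale * (x * upv[0] + y * upv[1] + z * upv[2]);
    pd[i] = depth_offset - (x * camdir[0] + y * camdir[1] + z * camdir[2]);
  }

  NumericMatrix R(nrow, ncol), G(nrow, ncol), B(nrow, ncol);
  NumericMatrix depth(nrow, ncol);
  IntegerMatrix faceid(nrow, ncol);
  std::fill(R.begin(), R.end(), bg[0]);
  std::fill(G.begin(), G.end(), bg[1]);
  std::fill(B.begin(), B.end(), bg[2]);
  std::fill(depth.begin(), depth.end(), R_PosInf);

  const int th = textured ? texdim[0] : 0, tw = textured ? texdim[1] : 0;

  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    const double ca = pc[a], cb = pc[b], cc = pc[c];
    const double ra = pr[a], rb = pr[b], rc = pr[c];
    // signed 2x area in (col,row) pixel space
    const double area = (cb - ca) * (rc - ra) - (cc - ca) * (rb - ra);
    if (std::fabs(area) < 1e-12) continue;  // degenerate in projection

    int rmin = (int)std::ceil(std::min(ra, std::min(rb, rc)));
    int rmax = (int)std::floor(std::max(ra, std::max(rb, rc)));
    int cmin = (int)std::ceil(std::min(ca, std::min(cb, cc)));
    int cmax = (int)std::floor(std::max(ca, std::max(cb, cc)));
    rmin = std::max(rmin, 1); cmin = std::max(cmin, 1);
    rmax = std::min(rmax, nrow); cmax = std::min(cmax, ncol);
    if (rmin > rmax || cmin > cmax) continue;

    // flat shading for untextured meshes: mesh-space normal vs camera dir
    double shade = 1.0;
    if (!textured) {
      double e1x = V(b,0)-V(a,0), e1y = V(b,1)-V(a,1), e1z = V(b,2)-V(a,2);
      double e2x = V(c,0)-V(a,0), e2y = V(c,1)-V(a,1), e2z = V(c,2)-V(a,2);
      double nx = e1y*e2z - e1z*e2y, ny = e1z*e2x - e1x*e2z,
             nz = e1x*e2y - e1y*e2x;
      double nn = std::sqrt(nx*nx + ny*ny + nz*nz);
      if (nn > 0) {
        double d = (nx*camdir[0] + ny*camdir[1] + nz*camdir[2]) / nn;
        shade = 0.15 + 0.85 * std::max(0.0, std::fabs(d));
      }
    }

    const double inv = 1.0 / area;
    for (int rr = rmin; rr <= rmax; ++rr) {
      for (int cccol = cmin; cccol <= cmax; ++cccol) {
        const double px = (double)cccol, py = (double)rr;
        double w0 = ((cb - ca) * (py - ra) - (px - ca) * (rb - ra)) * inv; // weight of c
        double w1 = ((px - ca) * (rc - ra) - (cc - ca) * (py - ra)) * inv; // weight of b
        // barycentric: P = a + w1*(b-a) + w0*(c-a)
        const double wa = 1.0 - w0 - w1;
        const double eps = -1e-9;
        if (wa < eps || w1 < eps || w0 < eps) continue;
        const double d = wa * pd[a] + w1 * pd[b] + w0 * pd[c];
        if (d < depth(rr - 1, cccol - 1)) {
          depth(rr - 1, cccol - 1) = d;
          faceid(rr - 1, cccol - 1) = f + 1;
          if (textured) {
            double u = wa * UV(a, 0) + w1 * UV(b, 0) + w0 * UV(c, 0);
            double v = wa * UV(a, 1) + w1 * UV(b, 1) + w0 * UV(c, 1);
            // OBJ vt origin is bottom-left; texture array row 1 is top
            int ti = (int)std::lround((1.0 - v) * (th - 1));
            int tj = (int)std::lround(u * (tw - 1));
            ti = std::min(std::max(ti, 0), th - 1);
            tj = std::min(std::max(tj, 0), tw - 1);
            R(rr - 1, cccol - 1) = tex[ti + th * tj];
            G(rr - 1, cccol - 1) = tex[ti + th * tj + th * tw];
            B(rr - 1, cccol - 1) = tex[ti + th * tj + 2 * th * tw];
          } else {
            R(rr - 1, cccol - 1) = shade;
            G(rr - 1, cccol - 1) = shade;
            B(rr - 1, cccol - 1) = shade;
          }
        }
      }
    }
  }

  return List::create(_["r"] = R, _["g"] = G, _["b"] = B,
                      _["depth"] = depth, _["faceid"] = faceid);
}

// Nearest ray-triangle intersection over every face (Moller-Trumbore).
// Edge and vertex hits are accepted via a small symmetric tolerance band so a
// ray crossing a shared edge registers once: among coincident hit distances
// the smallest face index wins (strict < with faces visited in order).
// Returns face = 0 when nothing is hit.
// [[Rcpp::export]]
List cpp_ray_cast(NumericMatrix V, IntegerMatrix F,
                  NumericVector orig, NumericVector dir) {
  const int nf = F.nrow();
  const double btol = 1e-9;
  double best_t = R_PosInf;
  int best_f = 0;
  double bu = 0, bv = 0;

  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    const double e1x = V(b,0)-V(a,0), e1y = V(b,1)-V(a,1), e1z = V(b,2)-V(a,2);
    const double e2x = V(c,0)-V(a,0), e2y = V(c,1)-V(a,1), e2z = V(c,2)-V(a,2);
    const double px = dir[1]*e2z - dir[2]*e2y;
    const double py = dir[2]*e2x - dir[0]*e2z;
    const double pz = dir[0]*e2y - dir[1]*e2x;
    const double det = e1x*px + e1y*py + e1z*pz;
    if (std::fabs(det) < 1e-14) continue;  // ray parallel to triangle plane
    const double invDet = 1.0 / det;
    const double tx = orig[0]-V(a,0), ty = orig[1]-V(a,1), tz = orig[2]-V(a,2);
    const double u = (tx*px + ty*py + tz*pz) * invDet;
    if (u < -btol || u > 1.0 + btol) continue;
    const double qx = ty*e1z - tz*e1y;
    const double qy = tz*e1x - tx*e1z;
    const double qz = tx*e1y - ty*e1x;
    const double v = (dir[0]*qx + dir[1]*qy + dir[2]*qz) * invDet;
    if (v < -btol || u + v > 1.0 + btol) continue;
    const double t = (e2x*qx + e2y*qy + e2z*qz) * invDet;
    if (t <= 1e-12) continue;  // behind the origin
    if (t < best_t) { best_t = t; best_f = f + 1; bu = u; bv = v; }
  }

  if (best_f == 0)
    return List::create(_["face"] = 0, _["t"] = R_PosInf,
                        _["point"] = R_NilValue, _["bary"] = R_NilValue);
  NumericVector pt(3);
  for (int k = 0; k < 3; ++k) pt[k] = orig[k] + best_t * dir[k];
  return List::create(_["face"] = best_f, _["t"] = best_t, _["point"] = pt,
                      _["bary"] = NumericVector::create(1.0 - bu - bv, bu, bv));
}
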