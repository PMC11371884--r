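#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel grid traversal (Amanatides & Woo) through a 3D integer label volume.
// Voxel (i,j,k) (0-based) is centered at world origin + (i,j,k)*spacing and
// spans +/- spacing/2 about its center.  Labels: 0 background, 1 condyle,
// 2 fossa.
//
// Status codes: 0 ok, 1 no_fossa, 2 no_condyle_exit, 3 out_of_volume.

static inline int label_at(const int* vox, const int* dim, int i, int j, int k) {
  return vox[i + dim[0] * (j + (long long)dim[1] * k)];
}

// Casts one ray; fills t_exit (condyle exit) and t_fossa (fossa entry) as
// parametric distances in mm (direction must be unit norm).
static int cast_one(const int* vox, const int* dim,
                    const double* spacing, const double* origin,
                    const double* p, const double* d,
                    double* t_exit, double* t_fossa) {
  const double INF = std::numeric_limits<double>::infinity();
  // continuous voxel coordinates of the ray origin
  double u[3];
  int idx[3], step[3];
  double tMax[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    u[a] = (p[a] - origin[a]) / spacing[a];
    idx[a] = (int)std::floor(u[a] + 0.5);   // voxel containing the point
    if (idx[a] < 0 || idx[a] >= dim[a]) return -1;  // origin outside grid
    if (d[a] > 0) {
      step[a] = 1;
      tMax[a] = ((idx[a] + 0.5) - u[a]) * spacing[a] / d[a];
      tDelta[a] = spacing[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      tMax[a] = (u[a] - (idx[a] - 0.5)) * spacing[a] / (-d[a]);
      tDelta[a] = spacing[a] / (-d[a]);
    } else {
      step[a] = 0;
      tMax[a] = INF;
      tDelta[a] = INF;
    }
  }

  int cur = label_at(vox, dim, idx[0], idx[1], idx[2]);
  bool in_condyle = (cur == 1);
  if (!in_condyle) return 2;            // ray must start inside the condyle
  bool have_exit = false;
  *t_exit = NA_REAL;
  *t_fossa = NA_REAL;

  while (true) {
    int a = 0;                          // axis of nearest face crossing
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double t_cross = tMax[a];
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dim[a]) {
      // ray leaves the grid
      return have_exit ? 1 : 3;         // no_fossa : out_of_volume
    }
    tMax[a] += tDelta[a];
    int lab = label_at(vox, dim, idx[0], idx[1], idx[2]);
    if (!have_exit) {
      if (lab != 1) {                   // first condyle -> non-condyle crossing
        have_exit = true;
        *t_exit = t_cross;
        if (lab == 2) { *t_fossa = t_cross; return 0; }  // fossa abuts condyle
      }
    } else if (lab == 2) {              // first subsequent fossa entry
      *t_fossa = t_cross;
      return 0;
    }
  }
}

// [[Rcpp::export(name = ".cast_rays_cpp")]]
List cast_rays_cpp(IntegerVector voxels, IntegerVector dim,
                   NumericVector spacing, NumericVector origin,
                   NumericVector point, NumericMatrix directions) {
  const int n = directions.nrow();
  IntegerVector status(n);
  NumericVector t_exit(n), t_fossa(n), gap(n);
  const int* vox = INTEGER(voxels);
  int dm[3] = { dim[0], dim[1], dim[2] };
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  double org[3] = { origin[0], origin[1], origin[2] };
  double p[3] = { point[0], point[1], point[2] };
  for (int r = 0; r < n; ++r) {
    double d[3] = { directions(r, 0), directions(r, 1), directions(r, 2) };
    double te = NA_REAL, tf = NA_REAL;
    int st = cast_one(vox, dm, sp, org, p, d, &te, &tf);
    if (st < 0) stop("ray origin lies outside the volume grid");
    status[r] = st;
    t_exit[r] = te;
    t_fossa[r] = tf;
    gap[r] = (st == 0) ? (tf - te) : NA_REAL;
  }
  return List::create(_["status"] = status, _["t_exit"] = t_exit,
                      _["t_fossa"] = t_fossa, _["gap"] = gap);
}
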