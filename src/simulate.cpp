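#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Brownian-dynamics loop for a sphere tethered to the plane z = 0.
//
// Forces: pull-only Hookean tethers (optionally two-sided), Stokes drag,
// thermal white noise. Gravity/buoyancy neglected. Non-penetration enforced
// by reflection at z = radius.
//
// Tether update per step, after the particle move: detachments first (elastic
// force strictly exceeding f_adh), then attachments (anchor tip within L0 of
// the plane, attachment at the perpendicular projection of the tip), tether
// index ascending in both passes.
//
// Uses R's RNG (norm_rand/unif_rand), so set.seed() on the R side gives
// bit-reproducible trajectories.

// [[Rcpp::export]]
List simulate_core(NumericMatrix anchors, double radius,
                   LogicalVector bound0, NumericVector attx0,
                   NumericVector atty0, NumericVector bindt0,
                   NumericVector pos0,
                   double gamma, double kBT, double kspring, double L0,
                   double f_adh, double dt, double n_steps_d,
                   NumericVector frame_steps,
                   double attach_prob, bool allow_compression,
                   bool inertial, double mass) {
  const int nt = anchors.nrow();
  const int nf = frame_steps.size();
  const double n_steps = n_steps_d;

  std::vector<double> ux(nt), uy(nt), uz(nt), ax(nt), ay(nt), bt(nt);
  std::vector<int> bound(nt);
  for (int i = 0; i < nt; ++i) {
    ux[i] = anchors(i, 0); uy[i] = anchors(i, 1); uz[i] = anchors(i, 2);
    bound[i] = bound0[i] ? 1 : 0;
    ax[i] = attx0[i]; ay[i] = atty0[i]; bt[i] = bindt0[i];
  }

  // bound tether indices, kept sorted ascending
  std::vector<int> bidx;
  for (int i = 0; i < nt; ++i) if (bound[i]) bidx.push_back(i);
  // anchor indices ordered by increasing tip height (uz ascending): the
  // attach scan walks this order and stops at the first tip out of reach
  std::vector<int> byheight(nt);
  for (int i = 0; i < nt; ++i) byheight[i] = i;
  std::sort(byheight.begin(), byheight.end(),
            [&](int a, int b) { return uz[a] < uz[b]; });

  double x = pos0[0], y = pos0[1], z = pos0[2];
  double vx = 0.0, vy = 0.0, vz = 0.0;

  NumericMatrix frames(nf, 3);
  IntegerVector frame_bound(nf);

  std::vector<double> ev_time;
  std::vector<int> ev_teth, ev_type;  // 1 = attach, 2 = detach

  const double sig_over = std::sqrt(2.0 * kBT * dt / gamma);

  // Exact constant-force Langevin update coefficients (inertial integrator):
  // velocity OU decay plus position increment with the exact joint covariance,
  // unconditionally stable, reduces to the overdamped update as lam*dt -> inf.
  double lam = 0.0, edt = 0.0, sv = 0.0, sx2 = 0.0, cvx = 0.0;
  if (inertial) {
    lam = gamma / mass;
    edt = std::exp(-lam * dt);
    sv = std::sqrt(kBT / mass * (1.0 - edt * edt));
    sx2 = kBT / (gamma * lam) *
          (2.0 * lam * dt - 3.0 + 4.0 * edt - edt * edt);
    cvx = kBT / gamma * (1.0 - edt) * (1.0 - edt);
  }

  std::vector<int> cand;
  cand.reserve(64);

  int fi = 0;
  // frames scheduled at step 0 (initial state)
  while (fi < nf && frame_steps[fi] <= 0.5) {
    frames(fi, 0) = x; frames(fi, 1) = y; frames(fi, 2) = z;
    int nb = 0; for (int i = 0; i < nt; ++i) nb += bound[i];
    frame_bound[fi] = nb;
    ++fi;
  }

  for (double s = 1.0; s <= n_steps; s += 1.0) {
    // total tether force on the particle centre
    double Fx = 0.0, Fy = 0.0, Fz = 0.0;
    for (size_t bi = 0; bi < bidx.size(); ++bi) {
      const int i = bidx[bi];
      const double tx = x + radius * ux[i];
      const double ty = y + radius * uy[i];
      const double tz = z + radius * uz[i];
      const double dx = ax[i] - tx, dy = ay[i] - ty, dz = -tz;
      const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dist < 1e-15) continue;
      const double ext = dist - L0;
      if (ext > 0.0 || allow_compression) {
        const double f = kspring * ext / dist;
        Fx += f * dx; Fy += f * dy; Fz += f * dz;
      }
    }

    if (!inertial) {
      x += Fx / gamma * dt + sig_over * norm_rand();
      y += Fy / gamma * dt + sig_over * norm_rand();
      z += Fz / gamma * dt + sig_over * norm_rand();
    } else {
      const double c1 = (1.0 - edt) / lam;
      // per axis: correlated (dv, dx) Gaussian pair
      double n1, n2, xiv, xix;
      n1 = norm_rand(); n2 = norm_rand();
      xiv = sv * n1;
      xix = (sv > 0.0 ? cvx / sv * n1 : 0.0) +
            std::sqrt(std::max(0.0, sx2 - (sv > 0.0 ? cvx * cvx / (sv * sv) : 0.0))) * n2;
      x += (vx - Fx / gamma) * c1 + Fx / gamma * dt + xix;
      vx = vx * edt + Fx / gamma * (1.0 - edt) + xiv;
      n1 = norm_rand(); n2 = norm_rand();
      xiv = sv * n1;
      xix = (sv > 0.0 ? cvx / sv * n1 : 0.0) +
            std::sqrt(std::max(0.0, sx2 - (sv > 0.0 ? cvx * cvx / (sv * sv) : 0.0))) * n2;
      y += (vy - Fy / gamma) * c1 + Fy / gamma * dt + xix;
      vy = vy * edt + Fy / gamma * (1.0 - edt) + xiv;
      n1 = norm_rand(); n2 = norm_rand();
      xiv = sv * n1;
      xix = (sv > 0.0 ? cvx / sv * n1 : 0.0) +
            std::sqrt(std::max(0.0, sx2 - (sv > 0.0 ? cvx * cvx / (sv * sv) : 0.0))) * n2;
      z += (vz - Fz / gamma) * c1 + Fz / gamma * dt + xix;
      vz = vz * edt + Fz / gamma * (1.0 - edt) + xiv;
    }

    // non-penetration of the substratum
    if (z < radius) {
      z = 2.0 * radius - z;
      if (inertial) vz = -vz;
    }

    const double tnow = s * dt;

    // detachments first (ascending tether index: bidx is sorted)
    if (R_finite(f_adh)) {
      for (size_t bi = 0; bi < bidx.size(); ) {
        const int i = bidx[bi];
        const double tx = x + radius * ux[i];
        const double ty = y + radius * uy[i];
        const double tz = z + radius * uz[i];
        const double dx = ax[i] - tx, dy = ay[i] - ty, dz = -tz;
        const double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
        const double ext = dist - L0;
        const double fmag = allow_compression ? kspring * std::fabs(ext)
                                              : kspring * std::max(0.0, ext);
        if (fmag > f_adh) {
          bound[i] = 0;
          bidx.erase(bidx.begin() + bi);
          ev_time.push_back(tnow); ev_teth.push_back(i + 1);
          ev_type.push_back(2);
        } else {
          ++bi;
        }
      }
    }

    // then attachments (reach rule), ascending tether index
    {
      cand.clear();
      for (int j = 0; j < nt; ++j) {
        const int i = byheight[j];
        const double tz = z + radius * uz[i];
        if (tz > L0) break;  // taller tips follow: none can be in reach
        if (!bound[i]) cand.push_back(i);
      }
      std::sort(cand.begin(), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        const int i = cand[c];
        if (attach_prob >= 1.0 || unif_rand() < attach_prob) {
          bound[i] = 1;
          ax[i] = x + radius * ux[i];
          ay[i] = y + radius * uy[i];
          bt[i] = tnow;
          bidx.insert(std::lower_bound(bidx.begin(), bidx.end(), i), i);
          ev_time.push_back(tnow); ev_teth.push_back(i + 1);
          ev_type.push_back(1);
        }
      }
    }

    while (fi < nf && std::fabs(frame_steps[fi] - s) < 0.5) {
      frames(fi, 0) = x; frames(fi, 1) = y; frames(fi, 2) = z;
      int nb = 0; for (int i = 0; i < nt; ++i) nb += bound[i];
      frame_bound[fi] = nb;
      ++fi;
    }
  }

  LogicalVector bound_out(nt);
  NumericVector ax_out(nt), ay_out(nt), bt_out(nt);
  for (int i = 0; i < nt; ++i) {
    bound_out[i] = bound[i] == 1;
    ax_out[i] = ax[i]; ay_out[i] = ay[i]; bt_out[i] = bt[i];
  }

  return List::create(
      _["frames"] = frames,
      _["frame_bound"] = frame_bound,
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["event_tether"] = IntegerVector(ev_teth.begin(), ev_teth.end()),
      _["event_type"] = IntegerVector(ev_type.begin(), ev_type.end()),
      _["final_position"] = NumericVector::create(x, y, z),
      _["final_bound"] = bound_out,
      _["final_attx"] = ax_out,
      _["final_atty"] = ay_out,
      _["final_bind_time"] = bt_out);
}
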