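#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Integrate one contiguous fine-resolution phase of the network with explicit
// Euler stepping: a stimulation session (training or recall) plus its trailing
// fine window. Rates, recurrent weights, excitability, the running windowed
// mean rate and the tag bookkeeping advance in lock-step.
//
// Update order within one step: (1) pre-activation from the state at step
// start, (2) Euler rate update + floor, (3) push rates into the averaging
// window, (4) Hebbian update, (5) tagging check, (6) due excitability jumps,
// (7) exact excitability relaxation over dt.
//
// The windowed mean is zero-padded: the circular buffer starts empty at phase
// onset, so the mean always divides by the full window length delta_avg.
//
// [[Rcpp::export(name = ".sim_fine_phase")]]
List sim_fine_phase(const arma::vec& r_init,
                    const arma::mat& W_init,
                    const arma::vec& eps_init,
                    const arma::vec& eps_base,
                    const arma::vec& ff_on,      // W^FF %*% r^in while the stimulus is on
                    const arma::ivec& stim_on,   // per-step 0/1, length n_steps
                    const arma::ivec& us_on,     // per-step 0/1
                    double us_plus,
                    const arma::vec& ext_stim,   // extra drive while stimulus on (partial cue)
                    const arma::vec& ext_always, // constant extra drive (i+ / eps+ windows)
                    double dt,
                    double tau_r, double tau_w, double tau_eps,
                    double i0, double i1,
                    const arma::vec& theta,      // per-neuron active threshold
                    double eps_jump, double tag_delay,
                    bool tagging,
                    bool apply_jumps,            // false: tags recorded, epsilon never moves
                    double fixed_jump_time,      // >= 0: absolute jump time (recall tagging)
                    double t0,
                    double delta_avg,
                    double rate_floor,
                    double w_min, double w_max,
                    bool plastic,
                    bool pre_gates_post,         // Hebbian orientation (see docs)
                    bool noise, double noise_amp,
                    int record_every) {
  const arma::uword n = r_init.n_elem;
  const arma::uword n_steps = stim_on.n_elem;

  arma::vec r = r_init;
  arma::mat W = W_init;
  arma::vec eps = eps_init;

  const arma::uword win_len = (arma::uword) std::llround(delta_avg / dt);
  arma::mat win(n, win_len, arma::fill::zeros);
  arma::vec win_sum(n, arma::fill::zeros);
  arma::uword win_pos = 0;

  LogicalVector tagged(n, false);
  NumericVector tag_time(n, NA_REAL);
  arma::vec jump_time(n);
  jump_time.fill(-1.0);                       // -1: no jump pending
  const double decay = std::exp(-dt / tau_eps);

  double max_rate = 0.0;
  arma::vec max_rate_i(n, arma::fill::zeros);

  arma::uword n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  arma::mat trace(n_rec, n);
  arma::vec trace_t(n_rec);
  arma::uword rec_i = 0;
  if (record_every > 0) {
    trace.row(rec_i) = r.t();
    trace_t(rec_i) = t0;
    ++rec_i;
  }

  arma::vec noise_v(n, arma::fill::zeros);
  arma::vec u(n), r0m(n);

  for (arma::uword s = 0; s < n_steps; ++s) {
    const bool on = stim_on(s) != 0;
    const double us = (us_on(s) != 0) ? us_plus : 0.0;
    const double t_now = t0 + (double)(s + 1) * dt;

    if (noise) {
      for (arma::uword i = 0; i < n; ++i)
        noise_v(i) = (R::unif_rand() - 0.5) * noise_amp;
    }

    const double inhib = i0 + i1 * arma::accu(r);
    u = W * r - inhib + eps + ext_always;
    if (on) u += ff_on + ext_stim;
    if (noise) u += noise_v;
    u.transform([](double v) { return v > 0.0 ? v : 0.0; });

    r += (dt / tau_r) * (u - r);
    r.transform([rate_floor](double v) { return v < rate_floor ? 0.0 : v; });
    if (!r.is_finite()) Rcpp::stop("non-finite firing rate at t = %f ms", t_now);

    const double rmax = r.max();
    if (rmax > max_rate) max_rate = rmax;
    max_rate_i = arma::max(max_rate_i, r);

    win_sum += r - win.col(win_pos);
    win.col(win_pos) = r;
    win_pos = (win_pos + 1) % win_len;
    r0m = win_sum * (dt / delta_avg);

    if (plastic && rmax > 0.0) {
      // pre_gates_post:  dW[i,j] ~ tanh(r_j * (r_i - r0_i))  (pre rate x post deviation)
      // otherwise:       dW[i,j] ~ tanh(r_i * (r_j - r0_j))  (post rate x pre deviation)
      const double g = (dt / tau_w) * (1.0 + us);
      if (pre_gates_post)
        W += g * arma::tanh((r - r0m) * r.t());
      else
        W += g * arma::tanh(r * (r - r0m).t());
      W.clamp(w_min, w_max);
    }

    if (tagging) {
      for (arma::uword i = 0; i < n; ++i) {
        if (!tagged[i] && r(i) >= theta(i)) {
          tagged[i] = true;
          tag_time[i] = t_now;
          if (apply_jumps)
            jump_time(i) = (fixed_jump_time >= 0.0) ? fixed_jump_time
                                                    : t_now + tag_delay;
        }
      }
    }

    // due excitability jumps: epsilon is SET to the elevated value
    for (arma::uword i = 0; i < n; ++i) {
      if (jump_time(i) >= 0.0 && t_now >= jump_time(i)) {
        eps(i) = eps_jump;
        jump_time(i) = -1.0;
      }
    }

    eps = eps_base + (eps - eps_base) * decay;

    if (record_every > 0 && ((s + 1) % (arma::uword)record_every == 0)) {
      trace.row(rec_i) = r.t();
      trace_t(rec_i) = t_now;
      ++rec_i;
    }
  }

  if (record_every > 0 && rec_i < n_rec) {
    trace = trace.rows(0, rec_i - 1);
    trace_t = trace_t.subvec(0, rec_i - 1);
  }

  return List::create(
    _["r"] = r, _["W"] = W, _["eps"] = eps,
    _["tagged"] = tagged,
    _["tag_time"] = tag_time,
    _["pending_jump_time"] = jump_time,   // -1 where none pending
    _["max_rate"] = max_rate,
    _["max_rate_neuron"] = max_rate_i,
    _["t_end"] = t0 + (double)n_steps * dt,
    _["trace"] = trace,
    _["trace_times"] = trace_t);
}

// Coarse inter-session stepping: recurrent weights frozen, rates advanced by
// explicit Euler at the coarse step, excitability relaxed exactly. Pending
// excitability jumps are applied at their scheduled times.
//
// [[Rcpp::export(name = ".sim_coarse_gap")]]
List sim_coarse_gap(const arma::vec& r_init,
                    const arma::mat& W,
                    const arma::vec& eps_init,
                    const arma::vec& eps_base,
                    double elapsed, double dt,
                    double tau_r, double tau_eps,
                    double i0, double i1,
                    double rate_floor,
                    const arma::vec& jump_time_init, // -1 where none pending
                    double eps_jump,
                    double t0,
                    bool noise, double noise_amp) {
  const arma::uword n = r_init.n_elem;
  arma::vec r = r_init;
  arma::vec eps = eps_init;
  arma::vec jump_time = jump_time_init;
  double max_rate = 0.0;

  double t = t0;
  const double t_end = t0 + elapsed;
  arma::vec u(n), noise_v(n, arma::fill::zeros);

  while (t < t_end - 1e-9) {
    const double step = std::min(dt, t_end - t);
    if (noise) {
      for (arma::uword i = 0; i < n; ++i)
        noise_v(i) = (R::unif_rand() - 0.5) * noise_amp;
    }
    u = W * r - (i0 + i1 * arma::accu(r)) + eps;
    if (noise) u += noise_v;
    u.transform([](double v) { return v > 0.0 ? v : 0.0; });
    r += (step / tau_r) * (u - r);
    r.transform([rate_floor](double v) { return v < rate_floor ? 0.0 : v; });
    const double rmax = r.max();
    if (rmax > max_rate) max_rate = rmax;

    t += step;
    eps = eps_base + (eps - eps_base) * std::exp(-step / tau_eps);
    for (arma::uword i = 0; i < n; ++i) {
      if (jump_time(i) >= 0.0 && t >= jump_time(i)) {
        eps(i) = eps_jump;
        jump_time(i) = -1.0;
      }
    }
  }

  return List::create(
    _["r"] = r, _["eps"] = eps,
    _["pending_jump_time"] = jump_time,
    _["max_rate"] = max_rate,
    _["t_end"] = t_end);
}
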