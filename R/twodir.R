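# 2D-IR response engine: numerical integration of the Schrodinger equation
# along the Hamiltonian trajectory, with two-quantum states treated
# perturbatively. The two-exciton wavepacket is carried as a symmetric N x N
# site-pair amplitude matrix C; harmonic (bosonic) propagation is then
# exactly C -> U C U^T built from one-exciton step propagators, and the site
# anharmonicity enters as an extra phase exp(+i*2*pi*c*Delta*dt) on the
# doubly-occupied diagonal after every step. Creation/annihilation follow the
# harmonic dipole-scaling rule, so at Delta = 0 the excited-state-absorption
# pathways cancel the bleach and stimulated-emission pathways identically.

# C_kl = m_k v_l + m_l v_k (includes the k = l double-occupation amplitude);
# annihilation is the adjoint contraction C %*% m
two_exciton_create <- function(m, v) {
  m <- as.complex(m)
  outer(m, v) + outer(v, m)
}

#' Rephasing and non-rephasing 2D-IR response functions
#'
#' Evaluates the ground-state-bleach, stimulated-emission and
#' excited-state-absorption pathways by chained one-exciton propagators along
#' the Hamiltonian trajectory, averaging over the three lab axes (the
#' isotropic j-sum) and over `n_starts` evenly spaced trajectory origins.
#' Lifetime damping `exp(-(t1+t3)/2T)` acts on the coherence intervals and
#' `exp(-T_w/T)` on the population interval.
#'
#' @param hs A `hamiltonian_series`.
#' @param t_w Wait time between pump and probe interactions (ps).
#' @param t1_max,t3_max Coherence-time windows (ps).
#' @param anharmonicity Site anharmonic shift Delta (cm^-1, >= 0); the
#'   doubly excited site lies at `2*w - Delta`.
#' @param lifetime_ps Amide I lifetime T (ps).
#' @param n_starts Trajectory origins averaged over (ignored for a single
#'   frame).
#' @param recycle Recycle the trajectory periodically when the propagation
#'   window `t1_max + t_w + t3_max` outruns it? If `FALSE`, such a call is an
#'   error.
#'
#' @return An object of class `twodir_response`: complex matrices
#'   `rephasing` and `nonrephasing` indexed by (t1, t3), the time axes, and
#'   the parameters.
#' @examples
#' h <- hamiltonian_series(matrix(1650), matrix(c(0.37, 0, 0), 1), dt_ps = 0.02)
#' r <- response_functions(h, t_w = 0, t1_max = 1, t3_max = 1,
#'                         anharmonicity = 16)
#' @export
response_functions <- function(hs, t_w = 0, t1_max = 2, t3_max = 2,
                               anharmonicity = 16, lifetime_ps = 1,
                               n_starts = 1L, recycle = TRUE) {
  if (anharmonicity < 0) abort("`anharmonicity` must be >= 0")
  dt <- hs$dt_ps
  nf <- dim(hs$hamiltonians)[3]
  n <- dim(hs$hamiltonians)[1]
  n1 <- ceiling(t1_max / dt) + 1L
  n3 <- ceiling(t3_max / dt) + 1L
  nw <- round(t_w / dt)
  span <- n1 + nw + n3
  if (!recycle && nf > 1L && span > nf) {
    abort("trajectory shorter than t1_max + t_w + t3_max; set recycle = TRUE or extend it")
  }
  omega_ref <- mean(apply(hs$hamiltonians, 3, function(m) mean(diag(m))))
  props <- frame_propagators(hs, omega_ref)
  anh_phase <- exp(1i * 2 * pi * C_CMPS * anharmonicity * dt)

  mu_at <- function(k) matrix(hs$dipoles[, , frame_at(k, nf)], ncol = 3L)
  u_at <- function(k) props[[frame_at(k, nf)]]

  r_tot <- matrix(0i, n1, n3)
  nr_tot <- matrix(0i, n1, n3)
  starts <- if (nf == 1L) 0L else {
    unique(floor(seq(0, max(0, nf - 1), length.out = n_starts)))
  }

  for (s0 in starts) {
    for (j in 1:3) {
      m0 <- mu_at(s0)[, j]
      # ket/bra chain from tau0 across the t1 grid
      chain0 <- matrix(0i, n, n1)
      psi <- as.complex(m0)
      for (k in seq_len(n1)) {
        chain0[, k] <- psi
        psi <- u_at(s0 + k - 1L) %*% psi
      }
      for (k1 in seq_len(n1)) {
        k_tau1 <- s0 + k1 - 1L
        m1 <- mu_at(k_tau1)[, j]
        s1 <- sum(m1 * chain0[, k1])          # <g|mu U(tau1,tau0) mu|g>
        # propagate both chains through the waiting time
        a2 <- chain0[, k1]                     # from tau0
        b2 <- as.complex(m1)                   # from tau1
        if (nw > 0L) {
          for (k in seq_len(nw)) {
            u <- u_at(k_tau1 + k - 1L)
            a2 <- u %*% a2
            b2 <- u %*% b2
          }
        }
        k_tau2 <- k_tau1 + nw
        m2 <- mu_at(k_tau2)[, j]
        f_se_r <- Conj(sum(a2 * m2))
        f_se_nr <- Conj(sum(b2 * m2))
        # t3 chains
        d3 <- as.complex(m2)                   # GSB detection chain
        a3 <- a2                               # bra for rephasing ESA
        e3 <- b2                               # SE-r ket / bra for NR ESA
        c_r <- two_exciton_create(m2, b2)
        c_nr <- two_exciton_create(m2, a2)
        for (k3 in seq_len(n3)) {
          k_tau3 <- k_tau2 + k3 - 1L
          m3 <- mu_at(k_tau3)[, j]
          det_gsb <- sum(m3 * d3)
          r_tot[k1, k3] <- r_tot[k1, k3] +
            Conj(s1) * det_gsb +                       # GSB rephasing
            f_se_r * sum(m3 * e3) -                    # SE rephasing
            sum(Conj(a3) * (c_r %*% m3))               # ESA rephasing
          nr_tot[k1, k3] <- nr_tot[k1, k3] +
            s1 * det_gsb +                             # GSB non-rephasing
            f_se_nr * sum(m3 * a3) -                   # SE non-rephasing
            sum(Conj(e3) * (c_nr %*% m3))              # ESA non-rephasing
          u <- u_at(k_tau3)
          d3 <- u %*% d3
          a3 <- u %*% a3
          e3 <- u %*% e3
          c_r <- u %*% c_r %*% t(u)
          c_nr <- u %*% c_nr %*% t(u)
          if (anharmonicity > 0) {
            diag(c_r) <- diag(c_r) * anh_phase
            diag(c_nr) <- diag(c_nr) * anh_phase
          }
        }
      }
    }
  }

  t1 <- (seq_len(n1) - 1) * dt
  t3 <- (seq_len(n3) - 1) * dt
  damp <- exp(-outer(t1, t3, `+`) / (2 * lifetime_ps)) *
    exp(-nw * dt / lifetime_ps)
  norm <- length(starts)
  structure(
    list(
      rephasing = r_tot * damp / norm,
      nonrephasing = nr_tot * damp / norm,
      t1 = t1, t3 = t3, t_w = nw * dt, dt_ps = dt,
      omega_ref = omega_ref, anharmonicity = anharmonicity,
      lifetime_ps = lifetime_ps
    ),
    class = "twodir_response"
  )
}

#' @export
print.twodir_response <- function(x, ...) {
  cat("<twodir_response> ", length(x$t1), " x ", length(x$t3),
      " time grid, T_w = ", x$t_w, " ps\n", sep = "")
  invisible(x)
}

#' Purely absorptive 2D-IR spectrum from time-domain responses
#'
#' Double Fourier transform over (t1, t3) with the omega_tau sign flipped for
#' the rephasing component, summed and truncated to the real part. Cosine
#' apodization and half-weighted t = 0 points give smooth grids; the
#' transform is evaluated directly on the requested frequency axes.
#'
#' @param resp A [response_functions()] result (carries both components).
#' @param omega_tau,omega_m Output axes (cm^-1).
#' @param apodize Apply the half-cosine window (default TRUE).
#' @return A [new_spectrum2d()] with `component = "absorptive"`.
#' @export
absorptive <- function(resp, omega_tau = seq(1600, 1700, 1),
                       omega_m = seq(1600, 1700, 1), apodize = TRUE) {
  if (!inherits(resp, "twodir_response")) {
    abort("`resp` must come from response_functions()")
  }
  w1 <- rep(1, length(resp$t1)); w1[1] <- 0.5
  w3 <- rep(1, length(resp$t3)); w3[1] <- 0.5
  if (apodize) {
    w1 <- w1 * cos(pi * resp$t1 / (2 * max(resp$t1)))
    w3 <- w3 * cos(pi * resp$t3 / (2 * max(resp$t3)))
  }
  rate <- 2 * pi * C_CMPS
  # rephasing: e^{-i w_tau t1}; non-rephasing: e^{+i w_tau t1}; both e^{+i w_m t3}
  e1_r <- exp(-1i * rate * outer(omega_tau - resp$omega_ref, resp$t1))
  e1_nr <- Conj(e1_r)
  e3 <- exp(1i * rate * outer(resp$t3, omega_m - resp$omega_ref))
  rw <- sweep(sweep(resp$rephasing, 1, w1, `*`), 2, w3, `*`)
  nrw <- sweep(sweep(resp$nonrephasing, 1, w1, `*`), 2, w3, `*`)
  s <- Re(e1_r %*% rw %*% e3 + e1_nr %*% nrw %*% e3) * resp$dt_ps^2
  new_spectrum2d(omega_tau, omega_m, s, t_w = resp$t_w,
                 component = "absorptive",
                 meta = list(anharmonicity = resp$anharmonicity,
                             lifetime_ps = resp$lifetime_ps))
}

#' Absorptive 2D-IR spectra at a series of wait times
#'
#' @param hs A `hamiltonian_series`.
#' @param t_w_list Wait times (ps); an empty list gives an empty result.
#' @param omega_tau,omega_m Output axes (cm^-1).
#' @param ... Passed to [response_functions()].
#' @return A list of [new_spectrum2d()], one per wait time, named by it.
#' @export
sweep_waittimes <- function(hs, t_w_list, omega_tau = seq(1600, 1700, 1),
                            omega_m = seq(1600, 1700, 1), ...) {
  out <- lapply(t_w_list, function(tw) {
    absorptive(response_functions(hs, t_w = tw, ...), omega_tau, omega_m)
  })
  names(out) <- as.character(unlist(t_w_list))
  out
}
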