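# Mean-field self-consistency, wave-regulation equilibrium, and capacity.
#
# All internal rates are in kHz (spikes/ms); user-facing firing rates are
# reported in Hz. The population rate splits as nu = nu_W + nu_S, background
# rates are lambda_E ~ C_E * nu and lambda_I = gamma' * lambda_E, the
# stochastic rate is the tabulated single-neuron response f_S, and the wave
# rate follows from the number of waves h through the propagation table:
# nu_W = (h / N_E) * n_E * p_f(lambda_E) / T(lambda_E).

clip_PS <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

#' Self-consistent mean-field state for a fixed number of waves
#'
#' Solves the background-rate fixed point
#' `lambda_E = C_E * ((h/N_E) * n_E * p_f(lambda_E) / T(lambda_E) +
#' f_S(lambda_E))` by bisection over the table support, returning the
#' smallest root (the low-rate asynchronous-irregular branch) together with
#' the implied rates and a stability flag for the stochastic-rate fixed
#' point (`|C_E * d f_S / d lambda_E| < 1`, derivative taken as a central
#' difference of the tabulated interpolant).
#'
#' @param C_E Excitatory inputs per neuron.
#' @param n_E Pool size (must be a row of the propagation table).
#' @param h_over_NE Number of propagating waves per excitatory neuron.
#' @param rates A [rate_table()] for `f_S`.
#' @param prop A [prop_table()] for `p_f` and `T`.
#' @param N_E Excitatory population size (with `h = h_over_NE * N_E`).
#' @return A `meanfield_solution`: `lambda_E`, `lambda_I` (kHz), `nu`,
#'   `nu_W`, `nu_S` (Hz), `h`, `residual`, `stable`.
#' @export
solve_selfconsistent <- function(C_E, n_E, h_over_NE, rates, prop,
                                 N_E = 10 * C_E) {
  if (h_over_NE < 0) stop_invalid("h_over_NE must be >= 0")
  gamma_prime <- attr(rates, "gamma_prime")
  wave_term <- if (h_over_NE > 0) {
    pf <- prop_row(prop, n_E, "p_f")
    Tf <- prop_row(prop, n_E, "T")
    function(lam) h_over_NE * n_E * pf(lam) / Tf(lam)
  } else function(lam) 0
  fS <- function(lam) fS_lookup(rates, lam) / 1000  # kHz
  resid <- function(lam) C_E * (wave_term(lam) + fS(lam)) - lam

  lo <- min(rates$lambda_E_kHz)
  hi <- max(rates$lambda_E_kHz)
  if (h_over_NE > 0) {
    i <- match(n_E, prop$n_E)
    ok <- !is.na(prop$p_f[i, ])
    lo <- max(lo, min(prop$lambda_E[ok]))
    hi <- min(hi, max(prop$lambda_E[ok]))
  }
  if (h_over_NE == 0 && resid(lo) <= 0 && lo <= 0) {
    lam <- 0
  } else {
    # smallest root: scan the table grid for the first + -> - sign change
    grid <- sort(unique(c(lo, rates$lambda_E_kHz, prop$lambda_E, hi)))
    grid <- grid[grid >= lo & grid <= hi]
    rg <- vapply(grid, resid, numeric(1))
    if (rg[1] <= 0) {
      lam <- if (rg[1] == 0) grid[1] else
        stop_invalid(paste0("no self-consistent solution: residual at ",
                            "bracket ends = %g (lambda=%g), %g (lambda=%g)"),
                     rg[1], grid[1], rg[length(rg)], grid[length(grid)])
    } else {
      k <- which(rg[-1] <= 0 & rg[-length(rg)] > 0)
      if (length(k) == 0)
        stop_invalid(paste0("no self-consistent solution: residual at ",
                            "bracket ends = %g (lambda=%g), %g (lambda=%g)"),
                     rg[1], grid[1], rg[length(rg)], grid[length(grid)])
      lam <- bisect(resid, grid[k[1]], grid[k[1] + 1], tol = 1e-12)
    }
  }
  nu_S <- fS(lam)
  nu_W <- wave_term(lam)
  dstep <- if (nrow(rates) > 1) min(diff(rates$lambda_E_kHz)) else 1
  d_fS <- (fS(min(hi, lam + dstep)) - fS(max(lo, lam - dstep))) /
    (min(hi, lam + dstep) - max(lo, lam - dstep))
  structure(list(lambda_E = lam, lambda_I = gamma_prime * lam,
                 nu = 1000 * (nu_W + nu_S), nu_W = 1000 * nu_W,
                 nu_S = 1000 * nu_S, h = h_over_NE * N_E,
                 C_E = C_E, n_E = n_E, N_E = N_E,
                 residual = resid(lam),
                 stable = abs(C_E * d_fS) < 1),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf(paste0("<meanfield_solution: lambda_E=%.4g kHz, nu=%.4g Hz ",
                     "(nu_W=%.4g, nu_S=%.4g), h=%.4g, %s>\n"),
              x$lambda_E, x$nu, x$nu_W, x$nu_S, x$h,
              if (x$stable) "stable" else "UNSTABLE"), ...)
  invisible(x)
}

#' Propagation threshold: maximum background rate and minimum pool size
#'
#' `lambda_E_max(n_E)` is the background rate at which the survival
#' probability of that pool size falls through 0.5 (linear interpolation
#' between the bracketing grid points of the first downward crossing);
#' `n_E_min(lambda_E)` is the inverse relation, interpolated on the pool
#' size axis. When a row never crosses 0.5 the nearest boundary value is
#' returned with `out_of_range = TRUE`.
#'
#' @param n_E Pool size (a row of the table).
#' @param prop A [prop_table()].
#' @return `lambda_E_max`: list `value` (kHz), `out_of_range`.
#' @export
lambda_E_max <- function(n_E, prop) {
  i <- match(n_E, prop$n_E)
  if (is.na(i)) stop_invalid("n_E = %g not a row of the table", n_E)
  ps <- prop$P_S[i, ]
  lam <- prop$lambda_E
  above <- ps > 0.5
  if (all(above)) return(list(value = max(lam), out_of_range = TRUE))
  if (!any(above)) return(list(value = min(lam), out_of_range = TRUE))
  k <- which(above[-length(above)] & !above[-1])[1]
  x0 <- lam[k]; x1 <- lam[k + 1]
  y0 <- ps[k]; y1 <- ps[k + 1]
  list(value = x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0), out_of_range = FALSE)
}

#' @rdname lambda_E_max
#' @param lambda_E Background rate (kHz).
#' @return `n_E_min`: list `value` (pool size), `out_of_range`.
#' @export
n_E_min <- function(lambda_E, prop) {
  lmax <- vapply(prop$n_E, function(n) lambda_E_max(n, prop)$value,
                 numeric(1))
  # lambda_E_max is increasing in n_E; invert monotonically
  if (lambda_E < min(lmax))
    return(list(value = prop$n_E[which.min(lmax)], out_of_range = TRUE))
  if (lambda_E > max(lmax))
    return(list(value = prop$n_E[which.max(lmax)], out_of_range = TRUE))
  o <- order(lmax)
  list(value = approx(lmax[o], prop$n_E[o], xout = lambda_E, ties = min)$y,
       out_of_range = FALSE)
}

#' Wave lifetime and equilibrium wave count at a given background rate
#'
#' Wave lifetimes are exponential with survival `P_S` over `L` pools, so the
#' expected lifetime is `T_S = T * L / log(1 / P_S)` and ongoing stimulation
#' every `T_stim` ms equilibrates at `h_eq = T_S / T_stim` waves. `P_S` is
#' clipped to `[1e-6, 1 - 1e-6]`; values at the clip bounds are flagged
#' `degenerate`.
#'
#' @param lambda_E Background rate (kHz).
#' @param n_E Pool size (a row of the table).
#' @param prop A [prop_table()].
#' @param T_stim Stimulation period (ms).
#' @param L Number of pools over which `P_S` was measured; default: the
#'   table's.
#' @return List `T_S` (ms), `h_eq`, `P_S`, `h_eq_approx` (using
#'   `T(lambda_E_max)` in place of `T(lambda_E)`), `degenerate`.
#' @export
equilibrium_waves <- function(lambda_E, n_E, prop, T_stim = 40, L = prop$L) {
  PSf <- prop_row(prop, n_E, "P_S")
  Tf <- prop_row(prop, n_E, "T")
  ps_raw <- PSf(lambda_E)
  ps <- clip_PS(ps_raw)
  TT <- Tf(lambda_E)
  T_S <- TT * L / log(1 / ps)
  That <- Tf(lambda_E_max(n_E, prop)$value)
  list(T_S = T_S, h_eq = T_S / T_stim, P_S = ps_raw,
       h_eq_approx = That * L / (T_stim * log(1 / ps)),
       degenerate = ps_raw <= 1e-6 || ps_raw >= 1 - 1e-6)
}

#' Equilibrium state of the stimulus-driven embedding
#'
#' The driven system equilibrates where the wave initiation rate
#' (`1 / T_stim`) balances the wave death rate, which pins the background
#' rate near the propagation threshold. The exact balance condition
#' `L * n_E * p_f(lambda) / (T_stim * log(1/P_S(lambda)) * N_E) =
#' lambda / C_E - f_S(lambda)` is solved by bisection over the sigmoidal
#' part of the survival curve; the simpler approximation evaluates all
#' quantities at `lambda = lambda_E_max(n_E)`. Both are returned.
#'
#' @param C_E Connectivity per neuron.
#' @param n_E Pool size (a row of the propagation table).
#' @param rates A [rate_table()].
#' @param prop A [prop_table()].
#' @param T_stim Stimulation period (ms).
#' @param N_E Excitatory population size.
#' @return List `exact` and `approx`, each containing `lambda_E`, `nu_Hz`,
#'   `nu_W_Hz`, `nu_S_Hz`, `h_eq`.
#' @export
equilibrium_state <- function(C_E, n_E, rates, prop, T_stim = 40,
                              N_E = 10 * C_E) {
  PSf <- prop_row(prop, n_E, "P_S")
  pf <- prop_row(prop, n_E, "p_f")
  Tf <- prop_row(prop, n_E, "T")
  L <- prop$L
  fS <- function(lam) fS_lookup(rates, lam) / 1000
  state_at <- function(lam) {
    ew <- equilibrium_waves(lam, n_E, prop, T_stim, L)
    nu_S <- fS(lam)
    nu_W <- (ew$h_eq / N_E) * n_E * pf(lam) / Tf(lam)
    list(lambda_E = lam, nu_Hz = 1000 * (nu_W + nu_S),
         nu_W_Hz = 1000 * nu_W, nu_S_Hz = 1000 * nu_S, h_eq = ew$h_eq)
  }
  balance <- function(lam) {
    ps <- clip_PS(PSf(lam))
    L * n_E * pf(lam) / (T_stim * log(1 / ps) * N_E) - (lam / C_E - fS(lam))
  }
  # bracket: the LHS diverges where P_S -> 1 and vanishes where P_S -> 0.
  # p_f and T are clamped to their measured support by the interpolants,
  # so the bracket may extend past the survival crossing even when no
  # trial survived there.
  lam_grid <- prop$lambda_E[prop$lambda_E >= min(rates$lambda_E_kHz) &
                              prop$lambda_E <= max(rates$lambda_E_kHz)]
  vals <- vapply(lam_grid, balance, numeric(1))
  k <- which(vals[-length(vals)] > 0 & vals[-1] <= 0)
  lam_exact <- if (length(k))
    bisect(balance, lam_grid[k[1]], lam_grid[k[1] + 1], tol = 1e-10)
  else stop_invalid(paste0("wave-regulation balance has no root on the ",
                           "table: balance = %g..%g"),
                    vals[1], vals[length(vals)])
  lam_apx <- lambda_E_max(n_E, prop)$value
  list(exact = state_at(lam_exact), approx = state_at(lam_apx))
}

#' Embedding-capacity curve versus connectivity
#'
#' For a specified level of activity the largest embedding level compatible
#' with stable propagation is `alpha_max = C_E / n_E_min^2`. Conditioning on
#' an equilibrium firing rate `nu_eq` sets the background rate at each
#' connectivity to `lambda = C_E * nu_eq` directly. Conditioning on a wave
#' density `h_eq / N_E` solves, per pool size, the pair of relations linking
#' the wave-regulation equilibrium (lifetime balance) and the background
#' self-consistency, giving a parametric `(C_E, alpha_max)` curve that is
#' interpolated onto the requested grid. Two connectivity limits are
#' reported: `C_E_max1`, where the stochastic-rate fixed point loses
#' stability (`C_E * d f_S/d lambda = 1`), and `C_E_max2`, where stochastic
#' spikes exceed half of all spiking.
#'
#' @param conditioning `"nu_eq"` or `"h_over_NE"`.
#' @param value The conditioning value: firing rate in Hz, or waves per
#'   excitatory neuron.
#' @param C_E_grid Ascending connectivities.
#' @param rates A [rate_table()].
#' @param prop A [prop_table()].
#' @param T_stim,L Wave-regulation constants (h-conditioning only).
#' @return A `capacity_curve` data frame (`C_E`, `lambda_E`, `n_E_min`,
#'   `alpha_max`, `nu_S_Hz`, `stable`, `wave_dominated`, `within_limits`)
#'   with attributes `C_E_max1`, `C_E_max2`.
#' @export
capacity_curve <- function(conditioning = c("nu_eq", "h_over_NE"), value,
                           C_E_grid, rates, prop, T_stim = 40, L = prop$L) {
  conditioning <- match.arg(conditioning)
  fS <- function(lam) fS_lookup(rates, lam) / 1000
  dstep <- min(diff(rates$lambda_E_kHz))
  lo <- min(rates$lambda_E_kHz); hi <- max(rates$lambda_E_kHz)
  d_fS <- function(lam) {
    a <- max(lo, lam - dstep); b <- min(hi, lam + dstep)
    (fS(b) - fS(a)) / (b - a)
  }
  if (conditioning == "nu_eq") {
    nu <- value / 1000  # kHz
    rows <- lapply(C_E_grid, function(CE) {
      lam <- CE * nu
      if (lam > hi || lam < lo)
        return(data.frame(C_E = CE, lambda_E = lam, n_E_min = NA_real_,
                          alpha_max = NA_real_, nu_S_Hz = NA_real_,
                          stable = NA, wave_dominated = NA))
      nm <- n_E_min(lam, prop)
      nu_S <- fS(lam)
      data.frame(C_E = CE, lambda_E = lam,
                 n_E_min = if (nm$out_of_range) NA_real_ else nm$value,
                 alpha_max = if (nm$out_of_range) NA_real_ else
                   CE / nm$value^2,
                 nu_S_Hz = 1000 * nu_S,
                 stable = abs(CE * d_fS(lam)) < 1,
                 wave_dominated = nu_S <= 0.5 * nu)
    })
    out <- do.call(rbind, rows)
  } else {
    v <- value
    # parametric in n_E: per pool size, solve the lifetime balance for
    # lambda, then read off the connectivity from the background
    # self-consistency with N_E = 10 * C_E
    pts <- lapply(prop$n_E, function(nE) {
      PSf <- prop_row(prop, nE, "P_S")
      pf <- prop_row(prop, nE, "p_f")
      Tf <- prop_row(prop, nE, "T")
      i <- match(nE, prop$n_E)
      lg <- prop$lambda_E[!is.na(prop$p_f[i, ])]
      lg <- lg[lg >= lo & lg <= hi]
      if (length(lg) < 2) return(NULL)
      # C_E from lifetime: h_eq = T*L/(T_stim*log(1/P_S)); v = h_eq/(10*C_E)
      CE_life <- function(lam)
        Tf(lam) * L / (T_stim * log(1 / clip_PS(PSf(lam))) * 10 * v)
      # C_E from background balance: lam = C_E*(v*10*... ) using
      # h/N_E = v: lam = C_E*(v*nE*pf/T + fS)
      CE_bal <- function(lam) lam / (v * nE * pf(lam) / Tf(lam) + fS(lam))
      g <- function(lam) CE_life(lam) - CE_bal(lam)
      vals <- vapply(lg, g, numeric(1))
      k <- which(sign(vals[-1]) * sign(vals[-length(vals)]) < 0)
      if (length(k) == 0) return(NULL)
      lam <- bisect(g, lg[k[1]], lg[k[1] + 1], tol = 1e-10)
      CE <- CE_bal(lam)
      nu_S <- fS(lam)
      nu <- lam / CE
      data.frame(C_E = CE, lambda_E = lam, n_E_min = nE,
                 alpha_max = CE / nE^2, nu_S_Hz = 1000 * nu_S,
                 stable = abs(CE * d_fS(lam)) < 1,
                 wave_dominated = nu_S <= 0.5 * nu)
    })
    pts <- do.call(rbind, pts)
    if (is.null(pts) || nrow(pts) < 2)
      stop_invalid("h-conditioning value outside table support")
    pts <- pts[order(pts$C_E), ]
    out <- data.frame(
      C_E = C_E_grid,
      lambda_E = approx(pts$C_E, pts$lambda_E, C_E_grid, rule = 1)$y,
      n_E_min = approx(pts$C_E, pts$n_E_min, C_E_grid, rule = 1)$y,
      alpha_max = approx(pts$C_E, pts$alpha_max, C_E_grid, rule = 1)$y,
      nu_S_Hz = approx(pts$C_E, pts$nu_S_Hz, C_E_grid, rule = 1)$y,
      stable = approx(pts$C_E, as.numeric(pts$stable), C_E_grid,
                      rule = 1)$y >= 0.5,
      wave_dominated = approx(pts$C_E, as.numeric(pts$wave_dominated),
                              C_E_grid, rule = 1)$y >= 0.5)
  }
  ok1 <- out$C_E[which(out$stable)]
  ok2 <- out$C_E[which(out$wave_dominated)]
  C1 <- if (length(ok1)) max(ok1) else NA_real_
  C2 <- if (length(ok2)) max(ok2) else NA_real_
  out$within_limits <- !is.na(out$alpha_max) &
    out$C_E <= min(C1, C2, na.rm = TRUE)
  structure(out, C_E_max1 = C1, C_E_max2 = C2, conditioning = conditioning,
            value = value, class = c("capacity_curve", "data.frame"))
}
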