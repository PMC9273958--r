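#' Packaged zero-variate trait observations for the hairtail
#'
#' The observed single-value life-history traits used to parameterize the
#' model (with the published prediction and relative-error columns kept for
#' reference), as shipped in
#' `system.file("extdata", "hairtail_zerovariate.csv", package = "debibm")`.
#'
#' @return a tibble with columns `trait`, `unit`, `observed`,
#'   `predicted_published`, `re_published`, `description`.
#' @examples
#' hairtail_traits()
#' @export
hairtail_traits <- function() {
  path <- system.file("extdata", "hairtail_zerovariate.csv", package = "debibm")
  readr::read_csv(path, show_col_types = FALSE)
}

# weight observable used by the trait layer: reserve taken at its
# equilibrium density e = E v_dot / (L^3 {p_Am} s_M) = f, i.e.
# E = f s_M {p_Am} / v_dot L^3, so W = L^3 (d_V + f s_M {p_Am}/(v_dot e_j)).
trait_weight <- function(L, s_M, f, pars) {
  L^3 * (pars$d_V + f * s_M * p_Am(pars) / (pars$v_dot * pars$e_j_content))
}

# lifespan: integrate growth + Weibull/Gompertz ageing from birth until
# survival drops to exp(-1)
solve_lifespan <- function(birth, juv, pars, f, T_K) {
  TC <- arrhenius_factor(T_K, pars)
  pAm <- p_Am(pars)
  E_m <- pAm / pars$v_dot
  rhs <- function(t, y, parms) {
    L <- y[1]; E <- y[2]; EH <- y[3]; q <- y[4]; h <- y[5]
    s_M <- min(max(1, L / birth$L_b), juv$s_M)
    v <- pars$v_dot * s_M
    pC <- TC * E * (pars$E_G * v * L^2 + pars$p_M_vol * L^3) /
      (pars$kappa * E + pars$E_G * L^3)
    pA <- TC * pAm * s_M * f * L^2
    dL <- max(pars$kappa * pC - TC * pars$p_M_vol * L^3, 0) /
      (3 * L^2 * pars$E_G)
    dEH <- if (EH < pars$E_Hp) (1 - pars$kappa) * pC - TC * pars$k_J_dot * EH else 0
    e_sc <- E / (L^3 * E_m)
    r <- 3 * dL / L
    L_m <- s_M * pars$z
    dq <- (q * (L / L_m)^3 * pars$s_G + pars$h_a_ddot) * e_sc *
      (TC * pars$v_dot * s_M / L - r) - r * q
    dh <- q - r * h
    list(c(dL, pA - pC, dEH, dq, dh, -h))
  }
  out <- deSolve::lsodar(
    y = c(L = birth$L_b, E = birth$E_b, EH = pars$E_Hb, q = 0, h = 0, lnS = 0),
    times = c(0, 60000 / TC), func = rhs, parms = NULL,
    rootfunc = function(t, y, parms) y[6] + 1,
    rtol = 1e-8, atol = c(1e-10, 1e-6, 1e-6, 1e-14, 1e-12, 1e-8)
  )
  n <- nrow(out)
  birth$a_b + out[n, 1]
}

#' Predict zero-variate traits from a DEB parameter set
#'
#' Computes the implied single-value life-history traits: the embryo is
#' solved with [initial_reserve()] (`a_b`, `L_b`, `W_b`), the juvenile
#' phases by adaptive integration to the metamorphosis and puberty
#' thresholds (`t_p`, `L_p`, `W_p`), the asymptotics from the acceleration
#' factor (`L_i`, `W_i`), the life span `a_m` from the Weibull/Gompertz
#' ageing hazard (survival down to `exp(-1)`), and the maximum reproduction
#' rate `R_i` and gonado-somatic index `GSI` from steady-state allocation.
#'
#' Lengths and weights are independent of the evaluation temperature; ages
#' and rates scale with the Arrhenius correction. Trait weights take the
#' reserve at its equilibrium density
#' `e = E v / (L^3 {p_Am} s_M) = f`.
#'
#' @param pars a [deb_params()] object.
#' @param f scaled functional response in `(0, 1]` (default 1).
#' @param T_eval evaluation temperature (K), default the reference
#'   temperature.
#' @param traits which traits to compute (default all); skipping `a_m`
#'   avoids the ageing-ODE integration, which matters inside calibration
#'   loops.
#' @return a `debibm_traits` tibble with columns `trait`, `unit`, `value`;
#'   attributes `s_M`, `E_0`, `f`, `T_eval`.
#' @examples
#' \donttest{
#' tr <- predict_traits(deb_params())
#' tr[tr$trait == "L_i", ] # ultimate preanal length, cm
#' }
#' @export
predict_traits <- function(pars, f = 1, T_eval = pars$T_ref,
                           traits = c("a_b", "t_p", "a_m", "L_b", "L_p",
                                      "L_i", "W_b", "W_p", "W_i", "GSI",
                                      "R_i")) {
  traits <- match.arg(traits, several.ok = TRUE)
  TC <- arrhenius_factor(T_eval, pars)
  birth <- initial_reserve(pars, f = f, T_K = T_eval)
  juv <- integrate_juvenile(birth, pars, f = f, T_K = T_eval)
  s_M <- juv$s_M
  L_i <- juv$L_i
  # steady-state allocation at ultimate size (reserve at actual density f)
  E_m <- p_Am(pars) / pars$v_dot
  p_C_i <- TC * f * E_m * L_i^3 *
    (pars$E_G * pars$v_dot * s_M * L_i^2 + pars$p_M_vol * L_i^3) /
    (pars$kappa * f * E_m * L_i^3 + pars$E_G * L_i^3)
  p_R_i <- (1 - pars$kappa) * p_C_i - TC * pars$k_J_dot * pars$E_Hp
  R_i <- max(0, pars$kappa_R * p_R_i / birth$E_0)
  # GSI: one year of reproduction output over body mass at the mean adult size
  L_bar <- (juv$L_p + L_i) / 2
  E_bar <- f * E_m * L_bar^3
  p_C_bar <- TC * E_bar *
    (pars$E_G * pars$v_dot * s_M * L_bar^2 + pars$p_M_vol * L_bar^3) /
    (pars$kappa * E_bar + pars$E_G * L_bar^3)
  p_R_bar <- max(0, (1 - pars$kappa) * p_C_bar - TC * pars$k_J_dot * pars$E_Hp)
  W_bar <- pars$d_V * L_bar^3 + E_bar / pars$e_j_content
  GSI <- pars$kappa_R * p_R_bar * 365 / (pars$e_j_content * W_bar)
  a_m <- if ("a_m" %in% traits) {
    solve_lifespan(birth, juv, pars, f, T_eval)
  } else NA_real_
  out <- tibble(
    trait = c("a_b", "t_p", "a_m", "L_b", "L_p", "L_i",
              "W_b", "W_p", "W_i", "GSI", "R_i"),
    unit = c("d", "d", "d", "cm", "cm", "cm", "g", "g", "g", "-", "1/d"),
    value = c(
      birth$a_b,
      juv$t_p,
      a_m,
      birth$L_b / pars$delta_M,
      juv$L_p / pars$delta_M,
      L_i / pars$delta_M,
      trait_weight(birth$L_b, 1, f, pars),
      trait_weight(juv$L_p, s_M, f, pars),
      trait_weight(L_i, s_M, f, pars),
      GSI,
      R_i
    )
  )
  out <- out[out$trait %in% traits, ]
  structure(out, class = c("debibm_traits", class(out)),
            s_M = s_M, E_0 = birth$E_0, f = f, T_eval = T_eval)
}

#' Trait report against observations
#'
#' Joins predicted traits to observed values and computes the per-trait
#' relative error `RE = |obs - pred| / |obs|` together with the MRE and SMSE
#' goodness-of-fit criteria.
#'
#' @param pars a [deb_params()] object.
#' @param observations a tibble with columns `trait` and `observed`
#'   (default [hairtail_traits()]).
#' @inheritParams predict_traits
#' @return a `debibm_traits` report tibble with columns `trait`, `unit`,
#'   `observed`, `predicted`, `re`; attributes `MRE` and `SMSE` (also
#'   available through [glance()]).
#' @examples
#' \donttest{
#' rep <- predict_trait_report(deb_params())
#' glance(rep)
#' }
#' @export
predict_trait_report <- function(pars, observations = hairtail_traits(),
                                 f = 1, T_eval = pars$T_ref) {
  pred <- predict_traits(pars, f = f, T_eval = T_eval)
  rep <- pred |>
    dplyr::rename(predicted = "value") |>
    left_join(select(observations, "trait", "observed"), by = "trait") |>
    mutate(re = abs(.data$observed - .data$predicted) / abs(.data$observed)) |>
    select("trait", "unit", "observed", "predicted", "re")
  tab <- tibble(dataset = rep$trait, observed = rep$observed,
                predicted = rep$predicted, weight = 1)
  gof <- goodness_of_fit(tab)
  structure(rep, class = c("debibm_traits", class(tibble())),
            MRE = gof$MRE, SMSE = gof$SMSE,
            s_M = attr(pred, "s_M"), E_0 = attr(pred, "E_0"),
            f = f, T_eval = T_eval)
}

#' @export
print.debibm_traits <- function(x, digits = 4, ...) {
  cat("# Zero-variate trait report (abj DEB)\n")
  NextMethod()
  if (!is.null(attr(x, "MRE"))) {
    cat(sprintf("# MRE = %.3f  SMSE = %.3f  (s_M = %.3f, E_0 = %.3f J)\n",
                attr(x, "MRE"), attr(x, "SMSE"),
                attr(x, "s_M"), attr(x, "E_0")))
  }
  invisible(x)
}

#' @method glance debibm_traits
#' @export
glance.debibm_traits <- function(x, ...) {
  tibble(MRE = attr(x, "MRE") %||% NA_real_,
         SMSE = attr(x, "SMSE") %||% NA_real_,
         s_M = attr(x, "s_M") %||% NA_real_,
         E_0 = attr(x, "E_0") %||% NA_real_,
         f = attr(x, "f") %||% NA_real_,
         T_eval = attr(x, "T_eval") %||% NA_real_)
}

#' @method tidy debibm_traits
#' @export
tidy.debibm_traits <- function(x, ...) as_tibble(x)

# ---- loss and goodness of fit ----------------------------------------------

check_data_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("dataset", "observed", "predicted") %in% names(table)))
  if (!"weight" %in% names(table)) {
    # Add-my-Pet default: weight 1/n_i within each dataset
    table <- table |>
      group_by(.data$dataset) |>
      mutate(weight = 1 / n()) |>
      ungroup()
  }
  if (any(table$weight < 0)) abort("negative weights in data table")
  table
}

#' Multiplicative symmetric bounded loss
#'
#' The estimation loss
#' \deqn{F = \sum_i \sum_j w_{ij} \frac{(d_{ij} - p_{ij})^2}{\bar d_i^2 + \bar p_i^2}}
#' where `j` indexes the points of dataset `i` and the normalization uses the
#' per-dataset means of data and predictions. `F` is zero iff all weighted
#' deviations vanish and is symmetric in data and predictions.
#'
#' @param table a data frame with columns `dataset`, `observed`, `predicted`
#'   and optionally `weight` (default `1/n_i` within each dataset).
#' @return the non-negative loss value.
#' @examples
#' loss_F(data.frame(dataset = "a", observed = 1, predicted = 3, weight = 1))
#' # (1-3)^2 / (1^2 + 3^2) = 0.4
#' @export
loss_F <- function(table) {
  table <- check_data_table(table)
  sets <- table |>
    group_by(.data$dataset) |>
    summarise(
      d_bar = mean(.data$observed), p_bar = mean(.data$predicted),
      num = sum(.data$weight * (.data$observed - .data$predicted)^2),
      w_tot = sum(.data$weight), .groups = "drop"
    )
  bad <- sets$d_bar^2 + sets$p_bar^2 == 0 & sets$w_tot > 0
  if (any(bad)) {
    abort(paste0("undefined loss normalization (all-zero means) in dataset(s): ",
                 paste(sets$dataset[bad], collapse = ", ")))
  }
  sum(sets$num / (sets$d_bar^2 + sets$p_bar^2))
}

#' Goodness-of-fit criteria
#'
#' The mean relative error (weighted mean of `|d - p| / |d|`) and the
#' symmetric mean squared error (weighted mean of `(d - p)^2 / (d^2 + p^2)`,
#' bounded in `[0, 1]`), following the Add-my-Pet definitions. Points with a
#' zero observation are excluded from the MRE with a warning.
#'
#' @inheritParams loss_F
#' @return a list with elements `MRE` and `SMSE`.
#' @examples
#' goodness_of_fit(data.frame(dataset = "L_i", observed = 89.6,
#'                            predicted = 68.7))
#' @export
goodness_of_fit <- function(table) {
  table <- check_data_table(table)
  zero <- table$observed == 0 & table$weight > 0
  if (any(zero)) {
    warn(sprintf("%d zero observation(s) excluded from MRE", sum(zero)))
  }
  mre_tab <- table[!zero, ]
  MRE <- with(mre_tab,
              sum(weight * abs(observed - predicted) / abs(observed)) /
                sum(weight))
  SMSE <- with(table,
               sum(weight * (observed - predicted)^2 /
                     (observed^2 + predicted^2)) / sum(weight))
  list(MRE = MRE, SMSE = SMSE)
}

#' Read or write a data table of observations
#'
#' CSV layout: `dataset`, `kind` (`zero` or `uni`), `x` (abscissa for
#' univariate sets, `NA` for zero-variate), `observed`, `weight`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_data_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("dataset", "observed") %in% names(tab)))
  tab
}

#' @rdname read_data_table
#' @param table the data table to write.
#' @export
write_data_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

# ---- calibration ------------------------------------------------------------

#' Calibrate DEB parameters against zero-variate traits
#'
#' Nelder-Mead minimization of [loss_F()] between observed traits and the
#' traits implied by the parameter vector, over a chosen free-parameter
#' subset. Parameters are optimized on the log scale, which keeps them
#' positive. The search is deterministic given the starting point and
#' tolerances.
#'
#' @param initial starting [deb_params()].
#' @param observations tibble with columns `trait`, `observed` and optionally
#'   `weight` (default weight 1 per trait, each trait its own dataset).
#' @param free character vector of parameter names to estimate (non-empty).
#' @param f,T_eval passed to [predict_traits()].
#' @param maxit maximum number of loss evaluations.
#' @param reltol relative convergence tolerance of the simplex.
#' @return a `debibm_fit` object; see [tidy()] and [glance()] methods.
#' @export
calibrate <- function(initial, observations, free,
                      f = 1, T_eval = initial$T_ref,
                      maxit = 300, reltol = 1e-6) {
  if (length(free) == 0L) abort("free parameter list is empty")
  bad <- setdiff(free, names(initial))
  if (length(bad)) abort(paste0("unknown free parameter(s): ",
                                paste(bad, collapse = ", ")))
  if (!"weight" %in% names(observations)) observations$weight <- 1
  want <- intersect(unique(observations$trait),
                    c("a_b", "t_p", "a_m", "L_b", "L_p", "L_i", "W_b", "W_p",
                      "W_i", "GSI", "R_i"))
  loss_of <- function(pars) {
    pred <- try(suppressWarnings(
      predict_traits(pars, f = f, T_eval = T_eval, traits = want)),
      silent = TRUE)
    if (inherits(pred, "try-error")) return(1e6)
    tab <- observations |>
      left_join(select(as_tibble(pred), "trait", "value"), by = "trait") |>
      filter(!is.na(.data$value))
    loss_F(tibble(dataset = tab$trait, observed = tab$observed,
                  predicted = tab$value, weight = tab$weight))
  }
  theta0 <- log(unlist(initial[free]))
  make_pars <- function(theta) {
    upd <- as.list(exp(theta))
    names(upd) <- free
    p <- unclass(initial)
    p[free] <- upd
    do.call(deb_params, p)
  }
  F0 <- loss_of(initial)
  opt <- suppressWarnings(
    optim(theta0, function(th) loss_of(make_pars(th)),
          method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = reltol))
  )
  best <- make_pars(opt$par)
  F1 <- min(opt$value, F0)
  if (opt$value > F0) best <- initial # descent guarantee
  structure(list(
    pars = best, initial = initial, free = free,
    F_initial = F0, F_final = F1,
    converged = opt$convergence == 0, evals = opt$counts[["function"]]
  ), class = "debibm_fit")
}

#' @export
print.debibm_fit <- function(x, ...) {
  cat(sprintf("<debibm_fit> F: %.5g -> %.5g (%s, %d evaluations)\n",
              x$F_initial, x$F_final,
              if (x$converged) "converged" else "max evaluations reached",
              x$evals))
  print(tidy(x))
  invisible(x)
}

#' @method tidy debibm_fit
#' @export
tidy.debibm_fit <- function(x, ...) {
  tibble(
    parameter = x$free,
    initial = unlist(x$initial[x$free]),
    estimate = unlist(x$pars[x$free])
  )
}

#' @method glance debibm_fit
#' @export
glance.debibm_fit <- function(x, ...) {
  tibble(F_initial = x$F_initial, F_final = x$F_final,
         converged = x$converged, evals = x$evals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
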