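#' @title Deterministic sensitivity analysis
#' @name sensitivity
#' @description
#' One-way and two-way sweeps of any transition probability, and
#' indifference-threshold root finding on the quality-adjusted (QALM)
#' objective. When a resection probability is overridden, the residual
#' branch absorbs the complement under a fixed rule: in the NAT pathway the
#' no-surgery branch absorbs it (exploratory surgery held at its baseline),
#' in the SF pathway the exploratory branch does. Because the rollup is
#' multilinear in each probability, one-way curves are exactly linear in the
#' swept parameter in direct-payoff mode.
NULL

split_param_id <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !(parts[1] %in% c("nat", "sf")))
    stop("parameter id must look like 'nat.p_resect' or 'sf.p_adjuvant', got '",
         id, "'")
  arm_params <- if (parts[1] == "nat") NAT_PARAMS else SF_PARAMS
  if (!(parts[2] %in% arm_params))
    stop("unknown parameter '", parts[2], "' for the ", toupper(parts[1]),
         " pathway")
  parts
}

#' Override one transition probability
#'
#' Returns a copy of the configuration with the named probability's point
#' estimate replaced. Residual branch masses are re-derived at tree-building
#' time, so overriding a resection probability automatically re-balances the
#' no-surgery (NAT) or exploratory (SF) complement; an override that would
#' drive any branch negative is an error.
#'
#' @param config A `model_config`.
#' @param id Parameter id, `"<arm>.<name>"`, e.g. `"nat.p_resect"`.
#' @param value New probability in \[0, 1\].
#' @return The modified `model_config`.
#' @export
apply_override <- function(config, id, value) {
  stopifnot(inherits(config, "model_config"))
  if (!is.finite(value) || value < 0 || value > 1)
    stop("override value must be a probability in [0, 1], got ", value)
  parts <- split_param_id(id)
  config$params[[parts[1]]][[parts[2]]]$point <- value
  validate_pathway_params(config$params)
  config
}

#' Range of a parameter as reported across source studies
#'
#' @param config A `model_config`.
#' @param id Parameter id (see [apply_override()]).
#' @return Length-2 numeric, the lowest and highest reported values.
#' @export
param_range <- function(config, id) {
  parts <- split_param_id(id)
  p <- config$params[[parts[1]]][[parts[2]]]
  c(p$range_low, p$range_high)
}

eval_objectives <- function(config, mode = "direct") {
  s <- evaluate_model(config, mode = mode)$summary
  c(sf_lm = s$life_months[s$strategy == "SF"],
    sf_qalm = s$qalms[s$strategy == "SF"],
    nat_lm = s$life_months[s$strategy == "NAT"],
    nat_qalm = s$qalms[s$strategy == "NAT"])
}

#' One-way deterministic sweep
#'
#' Evaluates both strategies at each grid point of one parameter, all other
#' parameters held at baseline.
#'
#' @param config A `model_config`.
#' @param id Parameter id.
#' @param lo,hi Sweep bounds (default: the parameter's reported range).
#' @param steps Number of grid points (>= 2).
#' @param mode Evaluation mode passed to [evaluate_model()].
#' @return A `data.frame` with columns `value`, `sf_lm`, `sf_qalm`,
#'   `nat_lm`, `nat_qalm`.
#' @export
one_way_sweep <- function(config, id, lo = NULL, hi = NULL, steps = 21,
                          mode = "direct") {
  rng <- param_range(config, id)
  if (is.null(lo)) lo <- rng[1]
  if (is.null(hi)) hi <- rng[2]
  if (!(lo < hi)) stop("lo must be strictly below hi")
  if (steps < 2) stop("need at least two grid points")
  grid <- seq(lo, hi, length.out = steps)
  vals <- t(vapply(grid, function(v)
    eval_objectives(apply_override(config, id, v), mode), numeric(4)))
  data.frame(value = grid, vals)
}

#' Indifference-threshold root finding
#'
#' Bisects the SF-minus-NAT difference in the chosen objective over an
#' interval of one parameter. If the difference does not change sign across
#' the interval, a result with an `NA` threshold is returned.
#'
#' @param config A `model_config`.
#' @param id Parameter id.
#' @param lo,hi Search bounds (default: the parameter's reported range).
#' @param tol Absolute tolerance on the parameter value (default 1e-4).
#' @param objective `"qalms"` (default) or `"life_months"`.
#' @param mode Evaluation mode.
#' @return An object of class `threshold_result`: list with `parameter`,
#'   `threshold` (NA if none), `superior_below`, `superior_above`,
#'   `objective`.
#' @export
find_threshold <- function(config, id, lo = NULL, hi = NULL, tol = 1e-4,
                           objective = c("qalms", "life_months"),
                           mode = "direct") {
  objective <- match.arg(objective)
  rng <- param_range(config, id)
  if (is.null(lo)) lo <- rng[1]
  if (is.null(hi)) hi <- rng[2]
  key <- if (objective == "qalms") c("sf_qalm", "nat_qalm") else c("sf_lm", "nat_lm")
  diff_at <- function(v) {
    o <- eval_objectives(apply_override(config, id, v), mode)
    o[[key[1]]] - o[[key[2]]]
  }
  f_lo <- diff_at(lo); f_hi <- diff_at(hi)
  winner <- function(d) if (d > 0) "SF" else if (d < 0) "NAT" else "tie"
  if (sign(f_lo) == sign(f_hi) || f_lo == f_hi) {
    return(structure(list(parameter = id, threshold = NA_real_,
                          superior_below = winner(f_lo),
                          superior_above = winner(f_hi),
                          objective = objective,
                          note = "no threshold in range"),
                     class = "threshold_result"))
  }
  a <- lo; b <- hi; fa <- f_lo
  while (b - a > tol) {
    mid <- (a + b) / 2
    fm <- diff_at(mid)
    if (fm == 0) { a <- b <- mid; break }
    if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  thr <- (a + b) / 2
  structure(list(parameter = id, threshold = thr,
                 superior_below = winner(f_lo),
                 superior_above = winner(f_hi),
                 objective = objective, note = NULL),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(x$parameter, ": no indifference threshold in range (",
        x$superior_below, " superior throughout)\n", sep = "")
  } else {
    cat(sprintf("%s: indifference at %.4f (%s superior below, %s above; %s)\n",
                x$parameter, x$threshold, x$superior_below, x$superior_above,
                x$objective))
  }
  invisible(x)
}

#' Two-way superiority map
#'
#' Evaluates the winning strategy on a grid over two parameters. Cells whose
#' absolute QALM (or life-month) difference is below `tie_tol` are marked
#' `"tie"`.
#'
#' @param config A `model_config`.
#' @param idA,idB Parameter ids for the rows (A) and columns (B).
#' @param gridA,gridB Monotone grids (default: 21 points over each
#'   parameter's reported range).
#' @param tie_tol Tie tolerance on the objective (default 0.01 QALM).
#' @param objective `"qalms"` (default) or `"life_months"`.
#' @return An object of class `superiority_map`: list with `gridA`, `gridB`,
#'   `winner` (matrix of `"SF"`/`"NAT"`/`"tie"`), `best_value` (matrix of the
#'   winning strategy's objective).
#' @export
two_way_map <- function(config, idA, idB, gridA = NULL, gridB = NULL,
                        tie_tol = 0.01, objective = c("qalms", "life_months")) {
  objective <- match.arg(objective)
  if (is.null(gridA)) {
    r <- param_range(config, idA); gridA <- seq(r[1], r[2], length.out = 21)
  }
  if (is.null(gridB)) {
    r <- param_range(config, idB); gridB <- seq(r[1], r[2], length.out = 21)
  }
  if (is.unsorted(gridA) || is.unsorted(gridB)) stop("grids must be monotone")
  key <- if (objective == "qalms") c("sf_qalm", "nat_qalm") else c("sf_lm", "nat_lm")
  winner <- matrix(NA_character_, length(gridA), length(gridB))
  best <- matrix(NA_real_, length(gridA), length(gridB))
  for (i in seq_along(gridA)) {
    cfgA <- apply_override(config, idA, gridA[i])
    for (j in seq_along(gridB)) {
      o <- eval_objectives(apply_override(cfgA, idB, gridB[j]))
      d <- o[[key[1]]] - o[[key[2]]]
      winner[i, j] <- if (abs(d) < tie_tol) "tie" else if (d > 0) "SF" else "NAT"
      best[i, j] <- max(o[[key[1]]], o[[key[2]]])
    }
  }
  structure(list(idA = idA, idB = idB, gridA = gridA, gridB = gridB,
                 winner = winner, best_value = best, tie_tol = tie_tol,
                 objective = objective),
            class = "superiority_map")
}

#' @export
print.superiority_map <- function(x, ...) {
  tab <- table(factor(x$winner, levels = c("SF", "NAT", "tie")))
  cat(sprintf("two-way map %s x %s (%d x %d cells): SF %d, NAT %d, tie %d\n",
              x$idA, x$idB, length(x$gridA), length(x$gridB),
              tab[["SF"]], tab[["NAT"]], tab[["tie"]]))
  invisible(x)
}
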