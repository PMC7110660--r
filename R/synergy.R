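#' @importFrom stats lm coef pt
NULL

#' Doubling time from a cell-count time course
#'
#' Least-squares fit of log2(count) against time; the doubling time is
#' the reciprocal of the fitted slope.
#'
#' @param times days, strictly increasing, length >= 3.
#' @param counts positive cell counts, same length as `times` (replicate
#'   measurements may be passed as a matrix with one column per
#'   replicate; the fit then pools all points).
#' @return doubling time in days per doubling.
#' @export
doublingTime <- function(times, counts) {
    counts <- as.matrix(counts)
    if (length(times) < 3) stop("need >= 3 timepoints")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
    if (any(counts <= 0)) stop("counts must be positive")
    tt <- rep(times, ncol(counts))
    slope <- coef(lm(log2(as.vector(counts)) ~ tt))[["tt"]]
    if (!is.finite(slope) || slope <= 0)
        stop("no net growth: fitted slope is not positive")
    1 / slope
}

#' Fractional decrease in proliferation
#'
#' `1 - mean(treated) / mean(control)`: the fraction by which a treatment
#' reduced proliferation relative to control.
#'
#' @param treated positive value(s) under treatment.
#' @param control positive value(s) without treatment (mean > 0).
#' @return fractional decrease (0.71 means a 71% reduction).
#' @export
fractionalDecrease <- function(treated, control) {
    mc <- mean(control)
    if (!is.finite(mc) || mc <= 0)
        stop("control mean must be positive")
    1 - mean(treated) / mc
}

#' Additive (independent-effects) null prediction
#'
#' Under Bliss independence the relative proliferation (survival
#' fraction) of independent treatments multiplies, so the predicted
#' combined fractional decrease is
#' \deqn{f_{pred} = 1 - (1 - f_a)(1 - f_b).}
#' E.g. a 71% decrease from radiation alone and a 42% decrease from
#' knockdown alone predict `1 - 0.29 * 0.58 = 0.8318`, i.e. 83%.
#'
#' @param f_a,f_b single-treatment fractional decreases in \[0, 1\]
#'   (vectorized; recycled).
#' @return predicted combined fractional decrease in \[0, 1\].
#' @export
additivePrediction <- function(f_a, f_b) {
    if (any(f_a < 0 | f_a > 1) || any(f_b < 0 | f_b > 1))
        stop("fractional decreases must be in [0, 1]")
    1 - (1 - f_a) * (1 - f_b)
}

.pooled_t <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2
    sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- mean(x) - mean(y)
    t <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-tailed synergy test against the additive null
#'
#' Tests whether the observed combined fractional decreases exceed the
#' additive-null prediction, with a two-sample, two-tailed,
#' pooled-variance Student's t test (df = n1 + n2 - 2). Predictions are
#' formed by pairing replicate-level single-treatment decreases when
#' `f_a`/`f_b` are vectors (recycled to the number of observed
#' replicates); a scalar prediction is replicated. The combination is
#' called synergistic iff the observed mean exceeds the predicted mean
#' and p < `alpha`.
#'
#' @param observed combined-treatment fractional decreases, one per
#'   replicate (length >= 2).
#' @param f_a,f_b single-treatment fractional decreases (scalars or
#'   per-replicate vectors). Ignored when `predicted` is given.
#' @param predicted optional pre-computed per-replicate predicted
#'   decreases, overriding `f_a`/`f_b`.
#' @param alpha significance level (default 0.05).
#' @return list of class `"SynergyResult"`: `f_rad` (= mean of `f_a`),
#'   `f_kd` (= mean of `f_b`), `f_obs`, `f_pred`, `t_stat`, `df`, `p`,
#'   `synergistic`.
#' @export
synergyTest <- function(observed, f_a = NULL, f_b = NULL,
                        predicted = NULL, alpha = 0.05) {
    if (length(observed) < 2) stop("need >= 2 observed replicates")
    if (is.null(predicted)) {
        if (is.null(f_a) || is.null(f_b))
            stop("either predicted or both f_a and f_b are required")
        predicted <- additivePrediction(f_a, f_b)
        if (length(predicted) == 1)
            predicted <- rep(predicted, length(observed))
    }
    tt <- .pooled_t(observed, predicted)
    res <- list(f_rad = if (is.null(f_a)) NA_real_ else mean(f_a),
                f_kd = if (is.null(f_b)) NA_real_ else mean(f_b),
                f_obs = mean(observed),
                f_pred = mean(predicted),
                t_stat = tt$t, df = tt$df, p = tt$p,
                synergistic = mean(observed) > mean(predicted) &&
                    tt$p < alpha)
    class(res) <- "SynergyResult"
    res
}

#' @export
print.SynergyResult <- function(x, ...) {
    cat(sprintf(
        "Synergy test: obs %.1f%% vs additive-null %.1f%% (A alone %.1f%%, B alone %.1f%%)\n",
        100 * x$f_obs, 100 * x$f_pred, 100 * x$f_rad, 100 * x$f_kd))
    cat(sprintf("  t = %.3f (df = %d), p = %.4g -> %s\n", x$t_stat, x$df,
                x$p, if (x$synergistic) "synergistic" else "not synergistic"))
    invisible(x)
}

#' @export
as.data.frame.SynergyResult <- function(x, ...) {
    data.frame(f_rad = x$f_rad, f_kd = x$f_kd, f_obs = x$f_obs,
               f_pred = x$f_pred, t_stat = x$t_stat, df = x$df, p = x$p,
               synergistic = x$synergistic)
}

#' Read a growth-assay table for synergy analysis
#'
#' Tab-separated with header `condition  replicate  value` and conditions
#' `control`, `A` (e.g. radiation alone), `B` (e.g. knockdown alone) and
#' `AB` (combined).
#'
#' @param path path to the TSV.
#' @return data.frame with those three columns.
#' @export
readSynergyTable <- function(path) {
    df <- .read_tsv(path)
    need <- c("condition", "replicate", "value")
    if (!all(need %in% colnames(df)))
        stop("synergy table must have columns: ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(df$condition), c("control", "A", "B", "AB"))
    if (length(bad))
        stop("unknown condition label(s): ", paste(bad, collapse = ", "))
    df
}

#' Synergy analysis of a control/A/B/AB growth assay
#'
#' Observed combined decreases are computed per replicate against the
#' mean of the control replicates. Per-replicate additive-null
#' predictions are formed batch-wise — each replicate's single-treatment
#' survival ratios are taken against that replicate's own control
#' measurement and multiplied — so that batch-level measurement noise
#' enters the prediction sample the way it enters the observations (this
#' pairing keeps the two-sample t test's type-I error at its nominal
#' level; see the package vignette). When replicate labels do not match
#' across conditions, the scalar prediction from the condition means is
#' replicated instead. The test itself is [synergyTest()].
#'
#' @param assay data.frame from [readSynergyTable()] (columns
#'   `condition`, `replicate`, `value`).
#' @param alpha significance level.
#' @return a `SynergyResult` (see [synergyTest()]).
#' @export
analyzeSynergy <- function(assay, alpha = 0.05) {
    val <- function(cond) {
        d <- assay[assay$condition == cond, , drop = FALSE]
        if (!nrow(d)) stop("condition '", cond, "' missing from assay table")
        d <- d[order(d$replicate), , drop = FALSE]
        structure(d$value, names = as.character(d$replicate))
    }
    ctrl <- val("control"); a <- val("A"); b <- val("B"); ab <- val("AB")
    mc <- mean(ctrl)
    if (mc <= 0) stop("control mean must be positive")
    obs <- 1 - ab / mc
    paired <- identical(names(a), names(b)) &&
        identical(names(a), names(ctrl)) &&
        length(a) == length(ab)
    pred <- if (paired) {
        1 - (a / ctrl) * (b / ctrl)
    } else {
        rep(1 - (mean(a) / mc) * (mean(b) / mc), length(obs))
    }
    res <- synergyTest(obs, predicted = pred, alpha = alpha)
    res$f_rad <- 1 - mean(a) / mc
    res$f_kd <- 1 - mean(b) / mc
    res
}
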