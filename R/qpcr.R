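#' Resection ssDNA percentage from a digested/mock Ct pair
#'
#' In the restriction-protection resection assay, double-stranded template is
#' cut by the enzyme while resected (single-stranded) template survives.
#' The surviving fraction is read out as
#' `ssDNA% = 1 / (2^(dCt - 1) + 0.5) * 100`, where
#' `dCt = ct_digested - ct_mock`. A negative dCt (digested amplifying
#' earlier than mock) is measurement noise near full protection and is
#' clamped to 0 with a flag rather than rejected.
#'
#' @param ct_digested,ct_mock Mean quantification cycles of the digested and
#'   mock-digested arms (average at least two replicates upstream).
#' @return List with `delta_ct` (after clamping), `ssdna_pct` and `clamped`.
#' @examples
#' ssdna_percent(20, 20)$ssdna_pct   # 100
#' ssdna_percent(21, 20)$ssdna_pct   # 66.67
#' @export
ssdna_percent <- function(ct_digested, ct_mock) {
  if (any(is.na(c(ct_digested, ct_mock)))) {
    stop("both the digested and the mock Ct are required", call. = FALSE)
  }
  dct <- ct_digested - ct_mock
  clamped <- dct < 0
  dct <- pmax(dct, 0)
  list(delta_ct = dct,
       ssdna_pct = 100 / (2^(dct - 1) + 0.5),
       clamped = clamped)
}

#' Inverse of the ssDNA formula: the dCt produced by a known fraction
#'
#' Solves `100 * f = 1 / (2^(dCt - 1) + 0.5) * 100` for `dCt`, giving
#' `dCt = log2(1/f - 0.5) + 1`. This is the generator side of the resection
#' round trip: a fraction of 1 maps to dCt = 0, a fraction of 0 to an
#' infinite dCt, which is capped at `ceiling` (the cap is recorded in the
#' `"capped"` attribute).
#'
#' @param f ssDNA fraction(s) in \[0, 1\].
#' @param ceiling Largest dCt emitted.
#' @return Numeric vector of dCt values with a logical `"capped"` attribute.
#' @examples
#' delta_ct_for_fraction(1)    # 0
#' delta_ct_for_fraction(0.5)  # log2(1.5) + 1
#' @export
delta_ct_for_fraction <- function(f, ceiling = 15) {
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) {
    stop("`f` must lie in [0, 1]", call. = FALSE)
  }
  dct <- ifelse(f == 0, Inf, log2(1 / f - 0.5) + 1)
  capped <- dct > ceiling
  out <- pmin(dct, ceiling)
  attr(out, "capped") <- capped
  out
}

#' Specify a synthetic resection qPCR panel
#'
#' Describes one condition's panel: the amplicons (targets plus negative
#' controls), the true ssDNA fraction and baseline Cq of each, and the
#' replicate/noise structure used by [simulate_qpcr_panel()].
#'
#' @param amplicons Data frame with columns `name` and `role`
#'   (`"target"` or `"negative_control"`).
#' @param fractions Named numeric vector of true ssDNA fractions in (0, 1],
#'   one per amplicon; negative-control amplicons must sit at or below
#'   0.005.
#' @param baseline_cq Named numeric vector of mock-digestion Cq values, one
#'   per amplicon (or a single value recycled to all).
#' @param replicates Technical replicates per arm, at least 2.
#' @param cq_noise_sd Gaussian noise SD applied to every well.
#' @param condition Condition label carried into the simulated table.
#' @param delta_ct_ceiling Cap passed to [delta_ct_for_fraction()].
#' @param seed Integer seed.
#' @return Object of class `qpcr_panel_spec`.
#' @export
qpcr_panel_spec <- function(amplicons, fractions, baseline_cq,
                            replicates = 3, cq_noise_sd = 0.1,
                            condition = "control", delta_ct_ceiling = 15,
                            seed = 1) {
  stopifnot(is.data.frame(amplicons),
            all(c("name", "role") %in% names(amplicons)))
  if (!all(amplicons$role %in% c("target", "negative_control"))) {
    stop("amplicon `role` must be \"target\" or \"negative_control\"",
         call. = FALSE)
  }
  if (anyDuplicated(amplicons$name)) {
    stop("amplicon names must be unique", call. = FALSE)
  }
  nm <- amplicons$name
  if (!all(nm %in% names(fractions))) {
    stop("every amplicon needs an entry in `fractions`", call. = FALSE)
  }
  fractions <- fractions[nm]
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("`fractions` must lie in (0, 1]", call. = FALSE)
  }
  neg <- amplicons$role == "negative_control"
  if (any(fractions[neg] > 0.005)) {
    stop("negative-control amplicons must have fraction <= 0.005",
         call. = FALSE)
  }
  if (length(baseline_cq) == 1L && is.null(names(baseline_cq))) {
    baseline_cq <- stats::setNames(rep(baseline_cq, length(nm)), nm)
  }
  if (!all(nm %in% names(baseline_cq))) {
    stop("every amplicon needs an entry in `baseline_cq`", call. = FALSE)
  }
  baseline_cq <- baseline_cq[nm]
  if (any(baseline_cq <= 0) || any(baseline_cq >= 45)) {
    stop("baseline Cq values must lie in (0, 45)", call. = FALSE)
  }
  if (replicates < 2) stop("`replicates` must be >= 2", call. = FALSE)
  if (cq_noise_sd < 0) stop("`cq_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(amplicons = amplicons, fractions = fractions,
         baseline_cq = baseline_cq, replicates = as.integer(replicates),
         cq_noise_sd = cq_noise_sd, condition = condition,
         delta_ct_ceiling = delta_ct_ceiling, seed = as.integer(seed)),
    class = "qpcr_panel_spec"
  )
}

#' Default resection panels for the two study conditions
#'
#' Five probes tiling each switch region at decreasing resection, plus one
#' non-targeted negative-control locus. The control condition sits in the
#' 0.5-3% ssDNA range typical of an unperturbed locus; the
#' repair-compromised ("knockdown") condition multiplies every target
#' fraction by `fold` (default 2.5).
#'
#' @param condition `"control"` or `"knockdown"`.
#' @param fold Fold increase of target fractions in the knockdown panel.
#' @param replicates,cq_noise_sd,seed Passed to [qpcr_panel_spec()].
#' @return A `qpcr_panel_spec`.
#' @export
default_resection_panel <- function(condition = c("control", "knockdown"),
                                    fold = 2.5, replicates = 3,
                                    cq_noise_sd = 0.1, seed = 1) {
  condition <- match.arg(condition)
  amplicons <- data.frame(
    name = c(paste0("Sd_p", 1:5), paste0("Sa_p", 1:5), "neg_ctrl"),
    role = c(rep("target", 10), "negative_control"),
    stringsAsFactors = FALSE
  )
  base_f <- c(Sd_p1 = 0.030, Sd_p2 = 0.020, Sd_p3 = 0.012,
              Sd_p4 = 0.008, Sd_p5 = 0.005,
              Sa_p1 = 0.025, Sa_p2 = 0.016, Sa_p3 = 0.010,
              Sa_p4 = 0.007, Sa_p5 = 0.005,
              neg_ctrl = 0.0005)
  if (condition == "knockdown") {
    tgt <- names(base_f) != "neg_ctrl"
    base_f[tgt] <- pmin(1, base_f[tgt] * fold)
  }
  baseline <- stats::setNames(
    c(21.5, 21.8, 22.1, 22.4, 22.7, 21.6, 21.9, 22.2, 22.5, 22.8, 24.0),
    amplicons$name
  )
  qpcr_panel_spec(amplicons, base_f, baseline, replicates = replicates,
                  cq_noise_sd = cq_noise_sd, condition = condition,
                  seed = seed)
}

#' Simulate raw Cq measurements for a resection panel
#'
#' Mock wells draw `baseline + noise`; digested wells draw
#' `baseline + dCt(f) + noise` with `dCt(f)` from
#' [delta_ct_for_fraction()] and i.i.d. Gaussian noise of SD
#' `cq_noise_sd`. All randomness flows from the panel specification's seed.
#'
#' @param spec A [qpcr_panel_spec()].
#' @return Long data frame (`sample`, `condition`, `amplicon`, `role`,
#'   `digestion`, `replicate`, `cq`) with the true fractions and dCt values
#'   in the `"truth"` attribute.
#' @export
simulate_qpcr_panel <- function(spec) {
  stopifnot(inherits(spec, "qpcr_panel_spec"))
  nm <- spec$amplicons$name
  dct <- delta_ct_for_fraction(spec$fractions, spec$delta_ct_ceiling)
  reps <- spec$replicates
  rows <- expand.grid(replicate = seq_len(reps),
                      digestion = c("mock", "digested"),
                      amplicon = nm,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- spec$baseline_cq[rows$amplicon]
  shift <- ifelse(rows$digestion == "digested", dct[rows$amplicon], 0)
  noise <- with_seed(spec$seed, stats::rnorm(nrow(rows), 0, spec$cq_noise_sd))
  out <- data.frame(
    sample = paste(spec$condition, rows$amplicon, sep = "_"),
    condition = spec$condition,
    amplicon = rows$amplicon,
    role = spec$amplicons$role[match(rows$amplicon, nm)],
    digestion = rows$digestion,
    replicate = rows$replicate,
    cq = as.numeric(base + shift + noise),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- data.frame(
    amplicon = nm, fraction = as.numeric(spec$fractions),
    delta_ct = as.numeric(dct), capped = attr(dct, "capped"),
    stringsAsFactors = FALSE
  )
  out
}

#' Resection profile: ssDNA percentage per amplicon and condition
#'
#' Averages replicate Cq values per (condition, amplicon, digestion) arm,
#' forms the digested-minus-mock dCt and converts it with
#' [ssdna_percent()]. When `control_condition` is given, each amplicon's
#' ssDNA% is also expressed as a fold change over the control condition.
#' Negative-control amplicons are reported but flagged so they are not read
#' as resection signal.
#'
#' @param panel Long Cq table as produced by [simulate_qpcr_panel()] (or
#'   any table with the same columns; a missing `role` column defaults to
#'   `"target"`).
#' @param control_condition Optional condition label used as the fold-change
#'   denominator.
#' @return Data frame: `condition`, `amplicon`, `role`, `n_replicates`,
#'   `cq_mock`, `cq_digested`, `cq_sd_mock`, `cq_sd_digested`, `delta_ct`,
#'   `clamped`, `ssdna_pct`, `negative_control`, `fold_vs_control`.
#' @export
resection_profile <- function(panel, control_condition = NULL) {
  need <- c("condition", "amplicon", "digestion", "replicate", "cq")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(panel$role)) panel$role <- "target"
  groups <- unique(panel[, c("condition", "amplicon", "role")])
  rownames(groups) <- NULL
  n <- nrow(groups)
  arm_stats <- function(cond, amp, dig) {
    v <- panel$cq[panel$condition == cond & panel$amplicon == amp &
                    panel$digestion == dig]
    if (length(v) == 0L) {
      stop(sprintf("missing %s arm for amplicon \"%s\" (condition \"%s\")",
                   dig, amp, cond), call. = FALSE)
    }
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  out <- groups
  out$n_replicates <- integer(n)
  out$cq_mock <- out$cq_digested <- numeric(n)
  out$cq_sd_mock <- out$cq_sd_digested <- numeric(n)
  out$delta_ct <- out$ssdna_pct <- numeric(n)
  out$clamped <- logical(n)
  for (i in seq_len(n)) {
    mk <- arm_stats(groups$condition[i], groups$amplicon[i], "mock")
    dg <- arm_stats(groups$condition[i], groups$amplicon[i], "digested")
    out$n_replicates[i] <- min(mk[["n"]], dg[["n"]])
    out$cq_mock[i] <- mk[["mean"]]; out$cq_sd_mock[i] <- mk[["sd"]]
    out$cq_digested[i] <- dg[["mean"]]; out$cq_sd_digested[i] <- dg[["sd"]]
    r <- ssdna_percent(dg[["mean"]], mk[["mean"]])
    out$delta_ct[i] <- r$delta_ct
    out$ssdna_pct[i] <- r$ssdna_pct
    out$clamped[i] <- r$clamped
  }
  if (any(out$n_replicates < 2)) {
    stop("each arm needs at least two replicates", call. = FALSE)
  }
  out$negative_control <- out$role == "negative_control"
  out$fold_vs_control <- NA_real_
  if (!is.null(control_condition)) {
    if (!control_condition %in% out$condition) {
      stop(sprintf("control condition \"%s\" not present in the panel",
                   control_condition), call. = FALSE)
    }
    ctrl <- out[out$condition == control_condition, ]
    idx <- match(out$amplicon, ctrl$amplicon)
    out$fold_vs_control <- out$ssdna_pct / ctrl$ssdna_pct[idx]
  }
  out
}

#' Relative expression by the ddCq method
#'
#' Per condition, the target Cq is normalised to a housekeeping gene:
#' `dCq = cq_target - cq_housekeeping`. With a control condition supplied,
#' the fold change is `2^-(dCq - dCq_ctrl)`; without one, the
#' single-condition expression level `2^-dCq` is returned.
#'
#' @param cq_target,cq_housekeeping Mean Cq of target and housekeeping
#'   amplicons in the condition of interest.
#' @param cq_target_ctrl,cq_housekeeping_ctrl Same for the control
#'   condition; supply both or neither.
#' @return Fold change (numeric scalar).
#' @examples
#' relative_expression(22, 20)  # 2^-2 = 0.25
#' @export
relative_expression <- function(cq_target, cq_housekeeping,
                                cq_target_ctrl = NULL,
                                cq_housekeeping_ctrl = NULL) {
  if (is.null(cq_target_ctrl) != is.null(cq_housekeeping_ctrl)) {
    stop("supply both control Cq values or neither", call. = FALSE)
  }
  dcq <- cq_target - cq_housekeeping
  if (is.null(cq_target_ctrl)) return(2^(-dcq))
  dcq_ctrl <- cq_target_ctrl - cq_housekeeping_ctrl
  2^(-(dcq - dcq_ctrl))
}

#' ChIP enrichment as percent of input
#'
#' The input Cq is first adjusted for the fraction of chromatin it
#' represents: `adjusted = cq_input - log2(1/input_fraction)`. Enrichment is
#' then `%input = 100 * 2^(adjusted - cq_ip)`.
#'
#' @param cq_input Mean Cq of the input sample.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @param cq_ip Mean Cq of the immunoprecipitated sample.
#' @return Percent of input (numeric scalar).
#' @examples
#' chip_percent_input(20, 1, 20)  # 100
#' @export
chip_percent_input <- function(cq_input, input_fraction, cq_ip) {
  if (!is.numeric(input_fraction) || is.na(input_fraction) ||
      input_fraction <= 0 || input_fraction > 1) {
    stop("`input_fraction` must lie in (0, 1]", call. = FALSE)
  }
  adjusted <- cq_input - log2(1 / input_fraction)
  100 * 2^(adjusted - cq_ip)
}
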