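#' Trim reaction times
#'
#' Applies the standard RT exclusion cascade to test-phase search trials:
#' incorrect responses are dropped, then RTs below 200 ms, then - per
#' subject, collapsed across conditions - RTs beyond 2.5 standard
#' deviations from that subject's mean (mean and SD computed after the
#' first two filters). Exclusion fractions are attached as attribute
#' `"trim_log"`.
#'
#' @param trials TrialTable with `rt` and `correct` columns (and
#'   optionally `subject`).
#' @param minRt lower RT cutoff in ms.
#' @param sdCut SD multiplier for the outlier rule.
#' @return the retained trials.
#' @export
trimRTs <- function(trials, minRt = 200, sdCut = 2.5) {
  stopifnot(all(c("rt", "correct") %in% names(trials)))
  if (!"subject" %in% names(trials)) trials$subject <- 1L
  search <- trials[trials$phase == "test" & !is.na(trials$rt), ,
                   drop = FALSE]
  n0 <- nrow(search)
  keep <- search[search$correct %in% TRUE, , drop = FALSE]
  nIncorrect <- n0 - nrow(keep)
  fast <- keep$rt < minRt
  nFast <- sum(fast)
  keep <- keep[!fast, , drop = FALSE]
  out <- do.call(rbind, lapply(split(keep, keep$subject), function(d) {
    mu <- mean(d$rt); s <- stats::sd(d$rt)
    if (is.na(s) || s == 0) return(d)
    d[abs(d$rt - mu) <= sdCut * s, , drop = FALSE]
  }))
  rownames(out) <- NULL
  attr(out, "trim_log") <- c(
    n_search = n0, n_incorrect = nIncorrect, n_fast = nFast,
    n_outlier = nrow(keep) - nrow(out),
    frac_excluded = if (n0 > 0) 1 - nrow(out) / n0 else 0)
  out
}

## Distractor condition of each test trial relative to the HPL, with the
## footnote rule: a trial counts as LPL only when neither the distractor
## nor the target occupies the HPL; distractor-at-LPL trials whose target
## sits on the HPL are excluded from the HPL/LPL contrast.
distractorCondition <- function(trials, hplBin) {
  cond <- rep(NA_character_, nrow(trials))
  absent <- !trials$distractor_present
  cond[absent] <- "absent"
  dHpl <- trials$distractor_present & trials$distractor_bin == hplBin
  cond[dHpl %in% TRUE] <- "hpl"
  lpl <- trials$distractor_present & trials$distractor_bin != hplBin &
    trials$target_bin != hplBin
  cond[lpl %in% TRUE] <- "lpl"
  excl <- trials$distractor_present & trials$distractor_bin != hplBin &
    trials$target_bin == hplBin
  cond[excl %in% TRUE] <- "excluded"
  cond
}

#' Per-subject condition summary of search behavior
#'
#' Computes the per-subject condition means used by the behavioral
#' analyses: distractor condition (absent / at the HPL / at an LPL, where
#' a trial counts as low-probability only when neither the target nor the
#' distractor occupies the HPL), target location (at vs not at the HPL,
#' collapsed across distractor presence), distractor distance from the
#' HPL (dist0..dist4), and distractor-location repetition. RT means use
#' trimmed trials ([trimRTs()]); accuracy means use all search trials.
#'
#' @param trials TrialTable (raw; trimming is applied internally for RT).
#' @param hplBin the high-probability bin.
#' @return a `BehaviorSummary` list of wide per-subject data.frames:
#'   `rt` and `acc` (columns per condition), `counts`, `hplBin`.
#' @export
conditionSummary <- function(trials, hplBin) {
  cfg <- attr(trials, "design_config")
  nb <- if (!is.null(cfg)) cfg$nLocations else 8L
  if (!hplBin %in% 0:(nb - 1)) stop("unknown hplBin", call. = FALSE)
  if (!"subject" %in% names(trials)) trials$subject <- 1L

  prep <- function(d) {
    d <- d[d$phase == "test" & !is.na(d$rt), , drop = FALSE]
    d$dcond <- distractorCondition(d, hplBin)
    d$tcond <- ifelse(d$target_bin == hplBin, "target_hpl", "target_lpl")
    d$dist <- binDistance(d$distractor_bin, hplBin, nb)
    d$rep <- ifelse(d$dist_repeat %in% TRUE, "repeat", "norepeat")
    d
  }
  trimmed <- prep(trimRTs(trials))
  allTrials <- prep(trials)

  agg <- function(d, value, by) {
    d <- d[!is.na(d[[by]]) & d[[by]] != "excluded", , drop = FALSE]
    stats::aggregate(d[[value]],
                     list(subject = d$subject, cond = d[[by]]),
                     mean)
  }
  wide <- function(long, prefix = "") {
    out <- stats::reshape(long, idvar = "subject", timevar = "cond",
                          direction = "wide")
    names(out) <- sub("^x\\.", prefix, names(out))
    rownames(out) <- NULL
    out
  }
  mergeAll <- function(parts) Reduce(function(a, b)
    merge(a, b, by = "subject", all = TRUE), parts)

  rtParts <- list(
    wide(agg(trimmed, "rt", "dcond")),
    wide(agg(trimmed, "rt", "tcond")),
    {
      dd <- trimmed[!is.na(trimmed$dist), , drop = FALSE]
      dd$dist <- paste0("dist", dd$dist)
      wide(agg(dd, "rt", "dist"))
    },
    wide(agg(trimmed[trimmed$distractor_present, ], "rt", "rep")))
  accLong <- allTrials
  accLong$acc <- 100 * (accLong$correct %in% TRUE)
  accParts <- list(
    wide(agg(accLong, "acc", "dcond")),
    wide(agg(accLong, "acc", "tcond")),
    {
      dd <- accLong[!is.na(accLong$dist), , drop = FALSE]
      dd$dist <- paste0("dist", dd$dist)
      wide(agg(dd, "acc", "dist"))
    },
    wide(agg(accLong[accLong$distractor_present, ], "acc", "rep")))

  counts <- table(allTrials$subject, allTrials$dcond)
  structure(list(rt = mergeAll(rtParts), acc = mergeAll(accParts),
                 counts = counts, hplBin = hplBin,
                 trim_log = attr(trimRTs(trials), "trim_log")),
            class = "BehaviorSummary")
}

## Greenhouse-Geisser epsilon from a subjects x conditions matrix, via
## normalized orthogonal contrasts of the sample covariance.
ggEpsilon <- function(M) {
  k <- ncol(M)
  S <- stats::cov(M)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                     # orthonormal (k x k-1)
  D <- t(C) %*% S %*% C
  sum(diag(D))^2 / ((k - 1) * sum(D^2))
}

## Paired t-test with Cohen's d (mean difference / SD of differences).
pairedT <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) {
    tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(c(t = tv, df = length(d) - 1,
             p = if (tv == 0) 1 else 0, d = tv, diff = mean(d)))
  }
  tt <- stats::t.test(d)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, d = mean(d) / stats::sd(d),
    diff = mean(d))
}

#' Group-level behavioral statistics
#'
#' Fills the test statistics of a [conditionSummary()]: planned paired
#' t-tests (distractor at HPL vs LPL, target at HPL vs LPL, repeat vs
#' non-repeat; RT and accuracy) with Cohen's d, and a one-way
#' repeated-measures ANOVA over the four distance conditions
#' (dist1..dist4) with Greenhouse-Geisser-corrected p-value and partial
#' eta squared, followed by Holm-Bonferroni-corrected pairwise
#' comparisons.
#'
#' @param summary a `BehaviorSummary`.
#' @return the summary with `$tests` (data.frame of paired contrasts),
#'   `$anova` (list per measure: `F`, `df`, `ggEpsilon`, `pGG`,
#'   `partialEta2`, `pairwise` with Holm-adjusted p) added.
#' @export
statsTests <- function(summary) {
  stopifnot(inherits(summary, "BehaviorSummary"))
  if (nrow(summary$rt) < 2)
    stop("need at least 2 subjects", call. = FALSE)

  contrasts <- list(
    rt_hpl_vs_lpl = c("rt", "hpl", "lpl"),
    rt_target_hpl_vs_lpl = c("rt", "target_hpl", "target_lpl"),
    rt_repeat_vs_norepeat = c("rt", "repeat", "norepeat"),
    acc_hpl_vs_lpl = c("acc", "hpl", "lpl"),
    acc_target_hpl_vs_lpl = c("acc", "target_hpl", "target_lpl"),
    acc_repeat_vs_norepeat = c("acc", "repeat", "norepeat"))
  tests <- do.call(rbind, lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    tab <- summary[[cc[1]]]
    res <- pairedT(tab[[cc[2]]], tab[[cc[3]]])
    data.frame(contrast = nm, t(res))
  }))

  rmAnova <- function(tab, lev) {
    M <- as.matrix(tab[, lev])
    n <- nrow(M); k <- ncol(M)
    long <- data.frame(
      y = as.vector(M),
      cond = factor(rep(lev, each = n)),
      subj = factor(rep(seq_len(n), k)))
    fit <- stats::aov(y ~ cond + Error(subj/cond), data = long)
    tabres <- summary(fit)[["Error: subj:cond"]][[1]]
    Fv <- tabres["cond", "F value"]
    df1 <- tabres["cond", "Df"]; df2 <- tabres["Residuals", "Df"]
    eps <- ggEpsilon(M)
    pGG <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    ss <- tabres[, "Sum Sq"]
    pairs <- utils::combn(lev, 2)
    praw <- apply(pairs, 2, function(pp)
      stats::t.test(tab[[pp[1]]], tab[[pp[2]]], paired = TRUE)$p.value)
    list(F = Fv, df = c(df1, df2), ggEpsilon = eps, pGG = pGG,
         partialEta2 = ss["cond"] / sum(ss),
         pairwise = data.frame(
           a = pairs[1, ], b = pairs[2, ], p_raw = praw,
           p_holm = stats::p.adjust(praw, "holm")))
  }
  lev <- paste0("dist", 1:4)
  summary$tests <- tests
  summary$anova <- list(rt = rmAnova(summary$rt, lev),
                        acc = rmAnova(summary$acc, lev))
  summary
}
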