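#' Common variants eligible for the association scan
#'
#' Applies the masking rules of the scan: a tested site must be a common
#' variant of the genealogy — minor-allele frequency at least `maf_min` on
#' the full haplotype panel — must not itself be causal, and — when
#' `fragment_exclusion` is on, as it is whenever recombination is
#' simulated — must not share a fragment with any causal site.
#'
#' "Common" is a property of the genealogy, not of the ascertained cohort:
#' frequencies are measured on the panel by default, so that rare variants
#' enriched in cases by the disease model cannot enter the common-variant
#' scan through ascertainment. Set `maf_source = "cohort"` to filter on the
#' cohort frequency instead.
#'
#' @param panel A `hap_panel`.
#' @param causal A `causal_set`.
#' @param cohort A `cohort` (its genotype columns define the candidate
#'   sites).
#' @param maf_min Minimum minor-allele frequency. Default 0.05.
#' @param fragment_exclusion Mask common sites sharing a fragment with a
#'   causal site.
#' @param maf_source Where the MAF filter is evaluated: `"panel"` (default)
#'   or `"cohort"`.
#' @return Integer vector of panel site indices, with a `masked` attribute:
#'   a data frame of excluded sites and the reason (`"causal"`,
#'   `"same_fragment_as_causal"`, `"maf_below_min"`).
#' @export
eligible_common_sites <- function(panel, causal, cohort, maf_min = 0.05,
                                  fragment_exclusion = FALSE,
                                  maf_source = c("panel", "cohort")) {
  maf_source <- match.arg(maf_source)
  sites <- cohort$site_index
  maf <- if (maf_source == "panel") {
    pmin(panel$freq[sites], 1 - panel$freq[sites])
  } else {
    fbar <- colMeans(cohort$genotypes) / 2
    pmin(fbar, 1 - fbar)
  }
  reason <- rep(NA_character_, length(sites))
  reason[maf < maf_min] <- "maf_below_min"
  if (fragment_exclusion && length(causal$sites)) {
    bad_frag <- unique(panel$fragment[causal$sites])
    reason[cohort$fragment %in% bad_frag] <- "same_fragment_as_causal"
  }
  reason[sites %in% causal$sites] <- "causal"
  keep <- is.na(reason)
  structure(sites[keep],
            masked = data.frame(site = sites[!keep], reason = reason[!keep]))
}

# Aggregate a cohort's genotype columns into case/control cell-count tables
# and fit per-site additive logistic regressions through the compiled
# Newton solver. `cov` is an optional per-individual covariate genotype.
scan_fit <- function(cohort, cols, cov = NULL) {
  g <- cohort$genotypes[, cols, drop = FALSE]
  status <- cohort$status
  if (is.null(cov)) {
    vals <- 0:2
    m_case <- g[status, , drop = FALSE]
    m_ctrl <- g[!status, , drop = FALSE]
    cc <- vapply(vals, function(v) colSums(m_case == v), numeric(ncol(g)))
    ct <- vapply(vals, function(v) colSums(m_ctrl == v), numeric(ncol(g)))
    gval <- as.numeric(vals); cval <- NULL
  } else {
    stopifnot(length(cov) == nrow(g), all(cov %in% 0:2))
    idx <- g + 3L * matrix(cov, nrow(g), ncol(g))
    vals <- 0:8
    m_case <- idx[status, , drop = FALSE]
    m_ctrl <- idx[!status, , drop = FALSE]
    cc <- vapply(vals, function(v) colSums(m_case == v), numeric(ncol(g)))
    ct <- vapply(vals, function(v) colSums(m_ctrl == v), numeric(ncol(g)))
    gval <- as.numeric(vals %% 3); cval <- as.numeric(vals %/% 3)
  }
  cc <- matrix(cc, ncol = length(vals))
  ct <- matrix(ct, ncol = length(vals))
  fit <- .logit_scan_counts(cc, ct, gval, cval)
  fit$maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  fit
}

#' Logistic-regression association scan
#'
#' Fits, for every requested site, a logistic regression of case/control
#' status on the additive genotype code (0/1/2 copies of the derived
#' allele), optionally adjusted for one covariate genotype. The reported
#' p-value is the Wald test of the genotype coefficient by default; a
#' likelihood-ratio test is available via `test = "lrt"` for
#' separation-prone sites. The odds ratio is `exp(beta)` exactly.
#'
#' Sites where the fit does not converge, separates completely, or is
#' collinear with the covariate are flagged and their p-value is `NA` —
#' never silently 0 or 1.
#'
#' @param cohort A `cohort`.
#' @param sites Panel site indices to test (must be among the cohort's
#'   genotype columns).
#' @param covariate Optional per-individual covariate genotype vector
#'   (values 0/1/2), e.g. the genotype of a conditioning site.
#' @param test `"wald"` (default) or `"lrt"`.
#' @param masked Optional masked-site registry (as produced by
#'   [eligible_common_sites()]) carried into the result for provenance.
#' @return An `assoc_table`: data frame with `site`, `pos`, `fragment`,
#'   `maf`, `beta`, `se`, `or`, `p`, `risk_allele` (`"derived"` or
#'   `"ancestral"`, the allele associated with higher disease probability)
#'   and `fit_status`; the masked registry is attached as attribute
#'   `masked`.
#' @export
logistic_scan <- function(cohort, sites, covariate = NULL,
                          test = c("wald", "lrt"), masked = NULL) {
  test <- match.arg(test)
  cols <- match(sites, cohort$site_index)
  if (anyNA(cols)) stop("some sites are not present in the cohort genotypes")
  if (length(cols) == 0L) {
    out <- data.frame(site = integer(0), pos = numeric(0), fragment = integer(0),
                      maf = numeric(0), beta = numeric(0), se = numeric(0),
                      or = numeric(0), p = numeric(0),
                      risk_allele = character(0), fit_status = character(0))
    attr(out, "masked") <- masked %||% data.frame(site = integer(0), reason = character(0))
    attr(out, "test") <- test
    class(out) <- c("assoc_table", "data.frame")
    return(out)
  }
  fit <- scan_fit(cohort, cols, covariate)
  ok <- fit$converged & !fit$separated & !fit$singular & is.finite(fit$se)
  p <- rep(NA_real_, length(cols))
  if (test == "wald") {
    p[ok] <- 2 * pnorm(-abs(fit$beta[ok] / fit$se[ok]))
  } else {
    lr <- 2 * (fit$loglik - fit$loglik_null)
    p[ok] <- pchisq(pmax(lr[ok], 0), df = 1, lower.tail = FALSE)
  }
  status <- ifelse(fit$singular, "singular",
                   ifelse(fit$separated, "separated",
                          ifelse(fit$converged, "ok", "not_converged")))
  out <- data.frame(site = as.integer(sites),
                    pos = cohort$positions[cols],
                    fragment = cohort$fragment[cols],
                    maf = fit$maf,
                    beta = ifelse(ok, fit$beta, NA_real_),
                    se = ifelse(ok, fit$se, NA_real_),
                    or = ifelse(ok, exp(fit$beta), NA_real_),
                    p = p,
                    risk_allele = ifelse(!ok, NA_character_,
                                         ifelse(fit$beta >= 0, "derived", "ancestral")),
                    fit_status = status)
  attr(out, "masked") <- masked %||% data.frame(site = integer(0), reason = character(0))
  attr(out, "test") <- test
  class(out) <- c("assoc_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conditional (secondary) association scan
#'
#' Re-runs the logistic scan with the genotype of `condition_site` included
#' as a covariate, to assess residual association once the strongest signal
#' is accounted for. `condition_site` itself is excluded from the tested
#' set; tested sites collinear with it are flagged, not errors.
#'
#' @inheritParams logistic_scan
#' @param condition_site Panel site index of the conditioning variant.
#' @return An `assoc_table` (see [logistic_scan()]).
#' @export
conditional_scan <- function(cohort, sites, condition_site,
                             test = c("wald", "lrt")) {
  col <- match(condition_site, cohort$site_index)
  if (is.na(col)) stop("condition_site not present in the cohort genotypes")
  sites <- setdiff(sites, condition_site)
  logistic_scan(cohort, sites, covariate = cohort$genotypes[, col],
                test = match.arg(test))
}

#' Strongest association in a scan
#'
#' @param table An `assoc_table`.
#' @return One-row data frame for the smallest finite p-value (ties broken
#'   by leftmost position), or `NULL` when no site has a finite p-value.
#' @export
top_hit <- function(table) {
  ok <- which(is.finite(table$p))
  if (!length(ok)) return(NULL)
  best <- ok[order(table$p[ok], table$pos[ok])][1]
  table[best, , drop = FALSE]
}

#' Distance to the most distal contributing causal site
#'
#' Implements the one-log-drop criterion: a causal site contributes to a
#' synthetic hit if refitting the hit's regression with that causal
#' genotype as a covariate raises the hit's p-value by at least one order
#' of magnitude. The returned distance is the largest
#' `|position(causal) - position(hit)|` over contributing sites, in bp;
#' `NA` when no causal site contributes.
#'
#' @param cohort A `cohort` whose genotype columns include the hit and the
#'   causal sites.
#' @param top_hit_site Panel site index of the (genome-wide significant)
#'   top common hit.
#' @param causal A `causal_set`.
#' @return Named list: `distance` (bp or `NA`), `contributing` (panel site
#'   indices), `p_unconditional`, `p_conditional` (per causal site).
#' @export
one_log_drop_distance <- function(cohort, top_hit_site, causal) {
  hit_col <- match(top_hit_site, cohort$site_index)
  if (is.na(hit_col)) stop("top_hit_site not present in the cohort genotypes")
  base <- logistic_scan(cohort, top_hit_site)
  p0 <- base$p[1]
  if (!is.finite(p0)) stop("unconditional fit of the top hit did not converge")
  pc <- vapply(causal$sites, function(s) {
    ccol <- match(s, cohort$site_index)
    if (is.na(ccol)) return(NA_real_)
    logistic_scan(cohort, top_hit_site,
                  covariate = cohort$genotypes[, ccol])$p[1]
  }, numeric(1))
  contributes <- !is.na(pc) & (log10(pc) - log10(p0) >= 1)
  dist <- if (any(contributes)) {
    hit_pos <- cohort$positions[hit_col]
    cc <- match(causal$sites[contributes], cohort$site_index)
    max(abs(cohort$positions[cc] - hit_pos))
  } else NA_real_
  list(distance = dist,
       contributing = causal$sites[contributes],
       p_unconditional = p0,
       p_conditional = pc)
}
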