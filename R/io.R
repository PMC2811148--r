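# Readers/writers for the standard text formats plus run manifests.
# Internal coordinates are 0-based bp offsets; VCF and the PLINK-style
# tables are written 1-based. Alleles are coded A = ancestral (REF),
# T = derived (ALT) throughout the exports.

#' Write an association table as a PLINK-style TSV
#'
#' Columns follow the PLINK `.assoc` convention (CHR, SNP, BP, A1, A2,
#' MAF, BETA, OR, SE, P) extended with `RISK_ALLELE`, `FIT_STATUS` and
#' `MASK_REASON`; masked sites are appended as rows with `NA` statistics
#' and their masking reason. Numbers are written in full double precision
#' so that [read_assoc_tsv()] round-trips losslessly.
#'
#' @param table An `assoc_table` from [logistic_scan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  tested <- data.frame(CHR = rep(1L, nrow(table)),
                       SNP = sprintf("site%d", table$site),
                       BP = floor(table$pos) + 1,
                       A1 = rep("T", nrow(table)),
                       A2 = rep("A", nrow(table)),
                       MAF = fmt(table$maf),
                       BETA = fmt(table$beta),
                       OR = fmt(table$or),
                       SE = fmt(table$se),
                       P = fmt(table$p),
                       POS0 = fmt(table$pos),
                       SITE = table$site,
                       FRAGMENT = table$fragment,
                       RISK_ALLELE = ifelse(is.na(table$risk_allele), "NA",
                                            table$risk_allele),
                       FIT_STATUS = table$fit_status,
                       MASK_REASON = rep("NA", nrow(table)),
                       stringsAsFactors = FALSE)
  masked <- attr(table, "masked")
  if (!is.null(masked) && nrow(masked)) {
    mrows <- data.frame(CHR = 1L,
                        SNP = sprintf("site%d", masked$site),
                        BP = NA_integer_,
                        A1 = "T", A2 = "A",
                        MAF = "NA", BETA = "NA", OR = "NA", SE = "NA",
                        P = "NA", POS0 = "NA",
                        SITE = masked$site,
                        FRAGMENT = NA_integer_,
                        RISK_ALLELE = "NA",
                        FIT_STATUS = "masked",
                        MASK_REASON = masked$reason,
                        stringsAsFactors = FALSE)
    tested <- rbind(tested, mrows)
  }
  write.table(tested, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_assoc_tsv()]
#'
#' @param path File path.
#' @return An `assoc_table` with the masked registry re-attached.
#' @export
read_assoc_tsv <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
  is_masked <- !is.na(raw$MASK_REASON)
  tested <- raw[!is_masked, ]
  out <- data.frame(site = as.integer(tested$SITE),
                    pos = as.numeric(tested$POS0),
                    fragment = as.integer(tested$FRAGMENT),
                    maf = as.numeric(tested$MAF),
                    beta = as.numeric(tested$BETA),
                    se = as.numeric(tested$SE),
                    or = as.numeric(tested$OR),
                    p = as.numeric(tested$P),
                    risk_allele = as.character(tested$RISK_ALLELE),
                    fit_status = tested$FIT_STATUS,
                    stringsAsFactors = FALSE)
  masked <- raw[is_masked, ]
  attr(out, "masked") <- data.frame(site = as.integer(masked$SITE),
                                    reason = masked$MASK_REASON,
                                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Export a haplotype panel as VCF
#'
#' Minimal VCF 4.2 with one haploid sample column per haplotype, the
#' ancestral allele as REF (`A`) and the derived allele as ALT (`T`).
#' POS is 1-based (`floor(offset) + 1`); the 0-based offset is kept in the
#' INFO field. A zero-site panel yields a header-only file.
#'
#' @param panel A `hap_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=synthassoc",
               sprintf("##contig=<ID=1,length=%d>",
                       as.integer(panel$params$region_length)),
               '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
               '##INFO=<ID=AF,Number=A,Type=Float,Description="Derived allele frequency">',
               '##INFO=<ID=OFFSET,Number=1,Type=Float,Description="0-based bp offset">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     sprintf("hap%d", seq_len(panel$n_hap))),
                   collapse = "\t"), con)
  if (n_sites(panel) > 0L) {
    gt <- matrix("0", nrow = n_sites(panel), ncol = panel$n_hap)
    for (j in seq_len(n_sites(panel))) gt[j, panel$carriers[[j]]] <- "1"
    lines <- paste(1L, floor(panel$positions) + 1,
                   sprintf("site%d", seq_len(n_sites(panel))),
                   "A", "T", ".", ".",
                   sprintf("AA=A;AF=%.6g;OFFSET=%.17g",
                           panel$freq, panel$positions),
                   "GT",
                   apply(gt, 1, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export a haplotype panel as a plain 0/1 matrix
#'
#' Whitespace-delimited text: a header line `positions` followed by the bp
#' offsets, then one row of 0/1 alleles per haplotype.
#'
#' @param panel A `hap_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_panel_matrix <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("positions", sprintf("%.17g", panel$positions)),
                   collapse = " "), con)
  m <- as.matrix(panel)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Export a cohort as PLINK .ped/.map
#'
#' Alleles are written `A` (ancestral) / `T` (derived); the phenotype
#' column is 1 = control, 2 = case.
#'
#' @param cohort A `cohort`.
#' @param prefix Output path prefix (`<prefix>.ped`, `<prefix>.map`).
#' @return The two file paths, invisibly.
#' @export
export_cohort_ped <- function(cohort, prefix) {
  map <- data.frame(chr = 1L,
                    snp = sprintf("site%d", cohort$site_index),
                    cm = 0,
                    bp = floor(cohort$positions) + 1)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- cohort$genotypes
  n <- nrow(g)
  a1 <- ifelse(g >= 1, "T", "A")
  a2 <- ifelse(g == 2, "T", "A")
  geno <- matrix(paste(a1, a2), nrow = n)
  ped <- cbind(sprintf("fam%d", seq_len(n)), sprintf("ind%d", seq_len(n)),
               "0", "0", "0", ifelse(cohort$status, "2", "1"), geno)
  writeLines(apply(ped, 1, paste, collapse = "\t"), paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Manhattan-plot data series
#'
#' @param table An `assoc_table`.
#' @return Data frame `pos`, `neglog10p`, sorted by position; sites with
#'   missing p-values are omitted.
#' @export
manhattan_data <- function(table) {
  ok <- is.finite(table$p)
  out <- data.frame(pos = table$pos[ok], neglog10p = -log10(table$p[ok]))
  out[order(out$pos), , drop = FALSE]
}

#' Write a JSON run manifest
#'
#' Records the parameter set, seeds, package version, replicate-level
#' counters and the output file inventory of a run, so that every random
#' draw is traceable to a recorded seed.
#'
#' @param path Output JSON path.
#' @param params Parameter object(s) (coerced via `unclass`).
#' @param seed Master seed of the run.
#' @param counters Named list of counters (redraws, aborts, flagged fits).
#' @param outputs Character vector of output files produced.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed = NULL,
                               counters = list(), outputs = character(0)) {
  manifest <- list(package = "synthassoc",
                   version = as.character(packageVersion("synthassoc")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   seed = seed,
                   params = lapply(if (inherits(params, c("sim_params",
                                                          "disease_spec")))
                                     list(params) else params, unclass),
                   counters = counters,
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
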