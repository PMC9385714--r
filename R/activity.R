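#' Assay specification for barcoded ligation sequencing
#'
#' Describes how reads of a ligation assay are interpreted: the barcodes
#' distinguishing the ligated and unligated pools (matched exactly at the
#' 5' end of the read), the constant flanks surrounding the variable
#' catalytic core, the core length, the per-read quality filter, and the
#' per-replicate depth filter.
#'
#' @param ligated_barcode,unligated_barcode Distinct barcode sequences
#'   (DNA) expected as the read prefix.
#' @param core_flank_5p,core_flank_3p Constant sequences flanking the
#'   variable core within the read (DNA).
#' @param core_length Length of the variable core (35 for the full
#'   catalytic core).
#' @param max_low_quality_bases Maximum number of base calls with
#'   quality score below 20 tolerated inside the core: 0 for the strict
#'   filter, 1 for the relaxation used for very large libraries.
#' @param min_total_reads Minimum `N_ligated + N_unligated` per replicate
#'   below which a variant is discarded (30 for the largest library, 100
#'   otherwise).
#' @return Object of class `assay_spec`.
#' @export
assay_spec <- function(ligated_barcode, unligated_barcode,
                       core_flank_5p, core_flank_3p,
                       core_length = 35L,
                       max_low_quality_bases = 1L,
                       min_total_reads = 100L) {
  stopifnot(nzchar(ligated_barcode), nzchar(unligated_barcode),
            ligated_barcode != unligated_barcode,
            core_length > 0L,
            max_low_quality_bases %in% c(0L, 1L),
            min_total_reads >= 0L)
  structure(list(ligated_barcode = ligated_barcode,
                 unligated_barcode = unligated_barcode,
                 core_flank_5p = core_flank_5p,
                 core_flank_3p = core_flank_3p,
                 core_length = as.integer(core_length),
                 max_low_quality_bases = as.integer(max_low_quality_bases),
                 min_total_reads = as.integer(min_total_reads)),
            class = "assay_spec")
}

#' Neutrality configuration
#'
#' A variant is called neutral when its mean relative activity reaches
#' the threshold (inclusive). The default of 0.2 reflects the
#' reproducibility limit of duplicate deep-sequencing measurements.
#'
#' @param threshold Positive RA threshold; `RA >= threshold` is neutral.
#' @return Object of class `neutrality_config`.
#' @export
neutrality_config <- function(threshold = 0.2) {
  stopifnot(is.numeric(threshold), threshold > 0)
  structure(list(threshold = threshold), class = "neutrality_config")
}

#' Read a FASTQ file into a read table
#'
#' Reads are DNA as sequenced; cores extracted from them are converted
#' to RNA downstream. Phred+33, 4-line records (plain or gzipped).
#'
#' @param path FASTQ path.
#' @return Data frame with columns `read_id`, `sequence`, and a list
#'   column `qualities` of per-base integer quality scores.
#' @importFrom methods as
#' @export
read_fastq <- function(path) {
  # the reader warns when dropping empty metadata columns; irrelevant here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  data.frame(read_id = names(x),
             sequence = as.character(x),
             qualities = I(as.list(quals)),
             stringsAsFactors = FALSE)
}

#' Sort reads into ligated and unligated pools by barcode
#'
#' Each read is assigned by exact match of the barcode at the start of
#' the read; reads matching neither barcode are rejected (rejects are
#' data, not errors, and are returned with a reason).
#'
#' @param reads Read table from [read_fastq()].
#' @param spec An [assay_spec()].
#' @return List with elements `ligated`, `unligated` (read tables) and
#'   `rejected` (read table with a `reason` column).
#' @export
demultiplex <- function(reads, spec) {
  stopifnot(inherits(spec, "assay_spec"))
  is_lig <- startsWith(reads$sequence, spec$ligated_barcode)
  is_unl <- !is_lig & startsWith(reads$sequence, spec$unligated_barcode)
  rejected <- reads[!is_lig & !is_unl, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- "no_barcode"
  list(ligated = reads[is_lig, , drop = FALSE],
       unligated = reads[is_unl, , drop = FALSE],
       rejected = rejected)
}

# Locate the variable core between the constant flanks of one read and
# apply the quality filter. Returns the RNA core or NA with a reason.
.extract_core_one <- function(sequence, qualities, spec) {
  hit <- regexpr(spec$core_flank_5p, sequence, fixed = TRUE)
  if (hit < 0L) return(list(core = NA_character_, reason = "flank5_missing"))
  start <- hit + nchar(spec$core_flank_5p)
  end <- start + spec$core_length - 1L
  f3_start <- end + 1L
  f3_end <- f3_start + nchar(spec$core_flank_3p) - 1L
  if (f3_end > nchar(sequence)) {
    return(list(core = NA_character_, reason = "truncated"))
  }
  if (substr(sequence, f3_start, f3_end) != spec$core_flank_3p) {
    return(list(core = NA_character_, reason = "flank3_mismatch"))
  }
  qs <- qualities[start:end]
  if (sum(qs < 20L) > spec$max_low_quality_bases) {
    return(list(core = NA_character_, reason = "low_quality"))
  }
  core <- chartr("T", "U", substr(sequence, start, end))
  if (grepl("[^ACGU]", core)) {
    return(list(core = NA_character_, reason = "ambiguous_base"))
  }
  list(core = core, reason = NA_character_)
}

#' Extract the variable catalytic core from reads
#'
#' Scans each read for the 5' flank, excises `core_length` bases, and
#' requires an exact 3' flank immediately after. Cores with more than
#' `max_low_quality_bases` base calls below quality score 20 are
#' rejected.
#'
#' @param reads Read table (e.g. one pool from [demultiplex()]).
#' @param spec An [assay_spec()].
#' @return Data frame with columns `read_id`, `core` (RNA sequence or
#'   `NA`) and `reason` (`NA` for accepted reads).
#' @export
extract_core <- function(reads, spec) {
  stopifnot(inherits(spec, "assay_spec"))
  res <- mapply(.extract_core_one, reads$sequence, reads$qualities,
                MoreArgs = list(spec = spec), SIMPLIFY = FALSE)
  data.frame(read_id = reads$read_id,
             core = vapply(res, `[[`, character(1L), "core"),
             reason = vapply(res, `[[`, character(1L), "reason"),
             stringsAsFactors = FALSE)
}

#' Fraction ligated
#'
#' `FL = N_ligated / (N_ligated + N_unligated)`, the per-variant readout
#' of the ligation assay.
#'
#' @param n_ligated,n_unligated Non-negative counts (vectorised).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
fraction_ligated <- function(n_ligated, n_unligated) {
  stopifnot(all(n_ligated >= 0), all(n_unligated >= 0))
  total <- n_ligated + n_unligated
  if (any(total == 0)) stop("zero total reads: fraction ligated undefined")
  n_ligated / total
}

#' Relative activity
#'
#' A variant's fraction ligated divided by the wild type's, so the wild
#' type maps to 1. Values above 1 indicate variants more active than the
#' wild type and are not capped.
#'
#' @param fl_variant Variant FL values (vectorised).
#' @param fl_wt Wild-type FL (> 0).
#' @return Numeric vector of RA values.
#' @export
relative_activity <- function(fl_variant, fl_wt) {
  stopifnot(length(fl_wt) == 1L)
  if (!is.finite(fl_wt) || fl_wt <= 0) {
    stop("wild-type fraction ligated must be positive")
  }
  fl_variant / fl_wt
}

#' Count variant cores per pool
#'
#' @param ligated_cores,unligated_cores Character vectors of accepted
#'   core sequences (rejected reads already removed).
#' @return Data frame with columns `sequence`, `n_ligated`,
#'   `n_unligated`.
#' @export
count_variants <- function(ligated_cores, unligated_cores) {
  seqs <- sort(unique(c(ligated_cores, unligated_cores)))
  tl <- table(factor(ligated_cores, levels = seqs))
  tu <- table(factor(unligated_cores, levels = seqs))
  data.frame(sequence = seqs,
             n_ligated = as.integer(tl),
             n_unligated = as.integer(tu),
             stringsAsFactors = FALSE)
}

#' Merge duplicate replicates into an activity table
#'
#' Applies the depth filter (a variant is discarded when the total read
#' count of either replicate is below `min_total_reads`), computes FL
#' and RA per replicate against the wild type included in the same
#' replicate, averages the duplicate RA values, and flags neutrality.
#' The duplicate standard deviation uses the population convention
#' (divisor n), i.e. `|RA1 - RA2| / 2`.
#'
#' @param counts Data frame with columns `sequence`, `replicate` (1 or
#'   2), `n_ligated`, `n_unligated`.
#' @param wt Wild-type core sequence; must pass the depth filter in both
#'   replicates.
#' @param spec An [assay_spec()] (depth filter).
#' @param cfg A [neutrality_config()].
#' @return Data frame of class `activity_table` with columns
#'   `variant_name`, `sequence`, `FL_rep1`, `FL_rep2`, `RA_rep1`,
#'   `RA_rep2`, `RA_mean`, `RA_sd`, `n_reads_rep1`, `n_reads_rep2`,
#'   `neutral`. Discarded variants are recorded in
#'   `attr(, "n_discarded")`.
#' @export
merge_replicates <- function(counts, wt, spec, cfg = neutrality_config()) {
  stopifnot(inherits(spec, "assay_spec"), inherits(cfg, "neutrality_config"),
            all(c("sequence", "replicate", "n_ligated", "n_unligated") %in%
                  names(counts)))
  if (!all(sort(unique(counts$replicate)) == c(1L, 2L))) {
    stop("exactly two replicates (1 and 2) are required")
  }
  r1 <- counts[counts$replicate == 1L, ]
  r2 <- counts[counts$replicate == 2L, ]
  seqs <- intersect(r1$sequence, r2$sequence)
  r1 <- r1[match(seqs, r1$sequence), ]
  r2 <- r2[match(seqs, r2$sequence), ]
  tot1 <- r1$n_ligated + r1$n_unligated
  tot2 <- r2$n_ligated + r2$n_unligated
  keep <- tot1 >= spec$min_total_reads & tot2 >= spec$min_total_reads
  n_discarded <- sum(!keep) + length(setdiff(union(counts$sequence, seqs), seqs))
  wi <- match(wt, seqs)
  if (is.na(wi) || !keep[wi]) {
    stop("wild type absent or below the depth filter in a replicate")
  }
  fl1 <- fraction_ligated(r1$n_ligated[keep], r1$n_unligated[keep])
  fl2 <- fraction_ligated(r2$n_ligated[keep], r2$n_unligated[keep])
  kseqs <- seqs[keep]
  wk <- match(wt, kseqs)
  ra1 <- relative_activity(fl1, fl1[wk])
  ra2 <- relative_activity(fl2, fl2[wk])
  ra_mean <- (ra1 + ra2) / 2
  ra_sd <- abs(ra1 - ra2) / 2
  out <- data.frame(
    variant_name = vapply(kseqs, function(s)
      name_variant(mutations_between(wt, s)), character(1L),
      USE.NAMES = FALSE),
    sequence = kseqs,
    FL_rep1 = fl1, FL_rep2 = fl2,
    RA_rep1 = ra1, RA_rep2 = ra2,
    RA_mean = ra_mean, RA_sd = ra_sd,
    n_reads_rep1 = tot1[keep], n_reads_rep2 = tot2[keep],
    neutral = ra_mean >= cfg$threshold,
    stringsAsFactors = FALSE)
  attr(out, "n_discarded") <- n_discarded
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Quantify activities from replicate FASTQ files
#'
#' Full read-level pipeline: demultiplex by barcode, extract and
#' quality-filter cores, count per pool, then merge the two replicates
#' into an activity table. Filter counts at every step are recorded in
#' `attr(, "filter_log")`.
#'
#' @param fastq_rep1,fastq_rep2 Paths to the replicate FASTQ files (each
#'   containing both pools, distinguished by barcode).
#' @param wt Wild-type core sequence.
#' @param spec An [assay_spec()].
#' @param cfg A [neutrality_config()].
#' @return An activity table, see [merge_replicates()].
#' @export
quantify_reads <- function(fastq_rep1, fastq_rep2, wt, spec,
                           cfg = neutrality_config()) {
  counts <- vector("list", 2L)
  log <- list()
  for (r in 1:2) {
    reads <- read_fastq(c(fastq_rep1, fastq_rep2)[r])
    pools <- demultiplex(reads, spec)
    lig <- extract_core(pools$ligated, spec)
    unl <- extract_core(pools$unligated, spec)
    cts <- count_variants(lig$core[!is.na(lig$core)],
                          unl$core[!is.na(unl$core)])
    cts$replicate <- r
    counts[[r]] <- cts
    log[[paste0("rep", r)]] <- list(
      n_reads = nrow(reads),
      n_no_barcode = nrow(pools$rejected),
      n_core_rejected = sum(is.na(lig$core)) + sum(is.na(unl$core)),
      core_reject_reasons = table(c(lig$reason, unl$reason), useNA = "no"))
  }
  out <- merge_replicates(do.call(rbind, counts), wt, spec, cfg)
  attr(out, "filter_log") <- log
  out
}

#' Read or write an activity table as TSV
#'
#' @param x Activity table.
#' @param path File path.
#' @param comments Optional provenance comment lines.
#' @export
write_activity_table <- function(x, path, comments = NULL) {
  write_tsv(as.data.frame(x), path, comments)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  x <- read_tsv(path)
  class(x) <- c("activity_table", "data.frame")
  x
}
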