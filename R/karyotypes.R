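#' @keywords internal
"_PACKAGE"

KARYO_CLASSES <- c("m", "sm", "st", "t")

#' Parse a karyotype formula string
#'
#' Parses a diploid karyotype formula in the Levan nomenclature, e.g.
#' \code{"12 m + 6sm + 4st"}, into counts per chromosome-morphology class.
#' Acrocentric (\code{a}) chromosomes are treated as telocentric (\code{t}).
#'
#' @param text A single karyotype formula string: \code{"+"}-separated terms of
#'   the form \code{<count><class>} with class one of \code{m}, \code{sm},
#'   \code{st}, \code{t}, \code{a}. Whitespace is arbitrary.
#' @return Named integer vector with elements \code{m}, \code{sm}, \code{st},
#'   \code{t}; classes absent from the formula are 0.
#' @examples
#' parse_karyotype("12 m + 6sm + 4st")
#' parse_karyotype("2 m + 6sm + 16st + 14 t")
#' @export
parse_karyotype <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("karyotype formula must be a single character string")
  s <- trimws(text)
  if (!nzchar(s)) stop("empty karyotype formula")
  terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1L]])
  counts <- stats::setNames(integer(4L), KARYO_CLASSES)
  for (term in terms) {
    if (!nzchar(term))
      stop("empty term in karyotype formula: ", sQuote(text))
    m <- regmatches(term, regexec("^([0-9]+)\\s*(sm|st|m|t|a)$", term))[[1L]]
    if (length(m) == 0L)
      stop("cannot parse karyotype term ", sQuote(term),
           " (expected <count><class> with class m/sm/st/t/a)")
    cls <- m[3L]
    if (cls == "a") cls <- "t"  # acrocentric recorded as telocentric
    counts[cls] <- counts[cls] + as.integer(m[2L])
  }
  counts
}

#' Format class counts back into a karyotype formula
#'
#' Inverse of [parse_karyotype()]: zero classes are omitted, so
#' \code{parse_karyotype(format_karyotype(x))} recovers \code{x}.
#'
#' @param counts Named vector with (a subset of) names m, sm, st, t.
#' @return A single formula string such as \code{"12m + 6sm + 4st"}.
#' @export
format_karyotype <- function(counts) {
  counts <- as_karyo_counts(counts)
  keep <- counts > 0L
  if (!any(keep)) stop("cannot format an all-zero karyotype")
  paste(paste0(counts[keep], names(counts)[keep]), collapse = " + ")
}

as_karyo_counts <- function(counts) {
  if (is.null(names(counts)))
    stop("class counts must be named (m, sm, st, t)")
  bad <- setdiff(names(counts), KARYO_CLASSES)
  if (length(bad))
    stop("unknown chromosome class: ", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(4L), KARYO_CLASSES)
  out[names(counts)] <- as.integer(round(counts))
  if (any(out < 0L)) stop("negative chromosome class count")
  out
}

#' Derive karyotype traits from diploid class counts
#'
#' Computes the quantitative karyotype traits used throughout the package
#' from diploid per-class chromosome counts: haploid number \code{n}, haploid
#' per-class counts \code{nm}, \code{nsm}, \code{nst}, \code{nt}, and the
#' fundamental number \code{fn} (arm count). \code{fn} is reported on the
#' DIPLOID scale, counting m/sm/st chromosomes as two-armed and t as
#' one-armed; the haploid arm count is \code{fn / 2}.
#'
#' @param counts Diploid class counts as returned by [parse_karyotype()].
#' @param strict If TRUE (default) an odd diploid count in any class is an
#'   error (all species analysed are diploid-karyotyped); if FALSE haploid
#'   counts may be half-integer.
#' @return Named numeric vector: n, nm, nsm, nst, nt, fn.
#' @examples
#' karyotype_traits(parse_karyotype("12 m + 10sm + 14st + 2 t"))
#' @export
karyotype_traits <- function(counts, strict = TRUE) {
  counts <- as_karyo_counts(counts)
  total <- sum(counts)
  if (total == 0L) stop("empty karyotype: all class counts are zero")
  if (strict && any(counts %% 2L != 0L))
    stop("odd diploid class count under strict mode: ",
         format_karyotype(counts))
  if (total %% 2L != 0L) stop("odd diploid total chromosome number")
  hap <- counts / 2
  c(n = total / 2,
    nm = unname(hap["m"]), nsm = unname(hap["sm"]),
    nst = unname(hap["st"]), nt = unname(hap["t"]),
    fn = unname(2 * (counts["m"] + counts["sm"] + counts["st"]) + counts["t"]))
}

#' Classify a chromosome by arm ratio
#'
#' Assigns the Levan morphology class from the long-arm/short-arm length
#' ratio r: metacentric (m) for r in [1, 1.7), submetacentric (sm) for
#' [1.7, 3), subtelocentric (st) for [3, 7), telocentric (t) for r >= 7 or a
#' missing short arm.
#'
#' @param long_arm,short_arm Arm lengths, \code{long_arm >= short_arm >= 0}.
#' @return One of "m", "sm", "st", "t".
#' @export
classify_arm_ratio <- function(long_arm, short_arm) {
  if (length(long_arm) != 1L || length(short_arm) != 1L)
    stop("classify_arm_ratio is scalar; vectorise with vapply()")
  if (long_arm <= 0 || short_arm < 0)
    stop("arm lengths must be positive (long) and non-negative (short)")
  if (long_arm < short_arm) stop("long arm shorter than short arm")
  if (short_arm == 0) return("t")
  r <- long_arm / short_arm
  if (r < 1.7) "m" else if (r < 3) "sm" else if (r < 7) "st" else "t"
}

#' Leafcutting-ant karyotype records
#'
#' Loads the packaged cytogenetic compilation for leafcutting ants
#' (Amoimyrmex, Atta, Acromyrmex) and three fungus-farming outgroups: one row
#' per published karyotype record with taxon, haploid/diploid number,
#' locality, diploid karyotype formula, genome size (Mbp, where available)
#' and the published haploid trait columns.
#'
#' Derived traits are recomputed from the formula with [karyotype_traits()];
#' records whose published fundamental number disagrees with the
#' two-armed-st convention (fn = 2(m+sm+st)+t on diploid counts) are flagged
#' with \code{fn_consistent = FALSE} and both values are kept
#' (\code{fn} derived, \code{fn_published} as printed).
#'
#' @param include_outgroups Keep the outgroup rows (default TRUE).
#' @return A data.frame with one row per record, including derived columns
#'   \code{n, nm, nsm, nst, nt, fn}, the published columns suffixed
#'   \code{_published}, \code{fn_consistent}, and \code{preferred} (the
#'   baseline record used per species: the first listed record).
#' @export
leafcutter_karyotypes <- function(include_outgroups = TRUE) {
  path <- system.file("extdata", "leafcutter_karyotypes.tsv",
                      package = "karyevo", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("taxon", "group", "haploid_n", "diploid_2n", "formula",
            "nm", "nsm", "nst", "nt", "fn")
  if (!all(need %in% names(raw)))
    stop("karyotype fixture is corrupt: missing columns ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (!include_outgroups) raw <- raw[raw$group != "outgroup", , drop = FALSE]
  der <- t(vapply(raw$formula,
                  function(f) karyotype_traits(parse_karyotype(f)),
                  numeric(6L)))
  out <- data.frame(
    taxon = raw$taxon, group = raw$group,
    haploid_n = raw$haploid_n, diploid_2n = raw$diploid_2n,
    locality = raw$locality, formula = raw$formula,
    genome_mbp = raw$genome_mbp,
    der,
    nm_published = raw$nm, nsm_published = raw$nsm,
    nst_published = raw$nst, nt_published = raw$nt,
    fn_published = raw$fn,
    stringsAsFactors = FALSE, row.names = NULL)
  out$fn_consistent <- out$fn == out$fn_published
  out$preferred <- !duplicated(out$taxon)
  stopifnot(all(out$n == out$haploid_n),
            all(out$nm + out$nsm + out$nst + out$nt == out$n))
  out
}

#' Per-species karyotype trait table
#'
#' Reduces a record table (one row per published record) to one trait vector
#' per species, using the preferred (baseline) record, optionally
#' log(x + 1)-transforming the trait columns (several traits contain zeros,
#' e.g. nt in Atta, so a plain log is undefined).
#'
#' @param records A record data.frame from [leafcutter_karyotypes()]; the
#'   default loads the packaged compilation.
#' @param log_transform Apply log(x + 1) to the trait columns.
#' @param include_outgroups Passed to [leafcutter_karyotypes()] when
#'   \code{records} is NULL.
#' @return data.frame with columns taxon, n, nm, nsm, nst, nt, fn; one row
#'   per species.
#' @export
karyotype_trait_table <- function(records = NULL, log_transform = FALSE,
                                  include_outgroups = TRUE) {
  if (is.null(records))
    records <- leafcutter_karyotypes(include_outgroups = include_outgroups)
  pref <- records[records$preferred, , drop = FALSE]
  stopifnot(!anyDuplicated(pref$taxon))
  out <- pref[, c("taxon", "n", "nm", "nsm", "nst", "nt", "fn")]
  row.names(out) <- NULL
  if (log_transform)
    out[-1L] <- lapply(out[-1L], function(x) log(x + 1))
  out
}

#' Write a trait table as TSV
#'
#' @param traits data.frame from [karyotype_trait_table()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
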