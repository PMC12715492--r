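#' Define a SNP panel
#'
#' A panel is the ordered set of biallelic SNPs genotyped in a study, with
#' the reference ("wild", more common) and alternative ("mutant", less
#' common) allele recorded per SNP. Allele labels are usually single
#' nucleotides but short strings such as the PAI-1 promoter labels
#' \code{"4G"}/\code{"5G"} are accepted.
#'
#' @param rsid character vector of SNP identifiers (unique).
#' @param gene character vector of gene symbols.
#' @param ref,alt character vectors of reference and alternative alleles;
#'   \code{ref[i] != alt[i]} for every SNP.
#' @return A data frame of class \code{"snp_panel"} with columns
#'   \code{rsid}, \code{gene}, \code{ref}, \code{alt}.
#' @examples
#' snp_panel("rs4961", "ADD1", "G", "T")
#' @export
snp_panel <- function(rsid, gene, ref, alt) {
  rsid <- as.character(rsid); gene <- as.character(gene)
  ref <- as.character(ref); alt <- as.character(alt)
  n <- length(rsid)
  if (length(gene) != n || length(ref) != n || length(alt) != n)
    stop_("rsid, gene, ref and alt must have equal length")
  if (anyDuplicated(rsid)) stop_("duplicate rsid in panel: ",
                                 paste(unique(rsid[duplicated(rsid)]), collapse = ", "))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop_("empty allele label")
  if (any(ref == alt)) stop_("ref and alt alleles must differ: ",
                             paste(rsid[ref == alt], collapse = ", "))
  structure(data.frame(rsid = rsid, gene = gene, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
            class = c("snp_panel", "data.frame"))
}

#' Read a SNP panel from a YAML or JSON configuration file
#'
#' The file holds a list of records with fields \code{rsid}, \code{gene},
#' \code{ref}, \code{alt}.
#'
#' @param path file path; format chosen by extension (\code{.json} parsed
#'   with jsonlite, anything else with yaml).
#' @return A \code{\link{snp_panel}}.
#' @export
read_panel <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  }
  snp_panel(recs$rsid, recs$gene, recs$ref, recs$alt)
}

#' Construct a matched case-control cohort
#'
#' Bundles pair-structured patient metadata with an alternative-allele dose
#' matrix and validates the matched design: every pair holds exactly one
#' case and one control of identical sex with ages within 5 years
#' (inclusive), and every patient belongs to exactly one pair.
#'
#' @param meta data frame with columns \code{patient_id}, \code{pair_id},
#'   \code{group} (\code{"case"}/\code{"control"}; case = phenotype
#'   present), \code{sex} (\code{"M"}/\code{"F"}), \code{age} (years, > 0),
#'   plus any numeric covariate columns.
#' @param genotypes integer matrix of alternative-allele doses (0, 1, 2 or
#'   \code{NA} for missing), rows named by \code{patient_id}, columns by
#'   rsid; every column must appear in \code{panel}.
#' @param panel a \code{\link{snp_panel}}.
#' @param age_tolerance maximum within-pair age difference (default 5,
#'   inclusive).
#' @return An object of class \code{"matched_cohort"}: a list with elements
#'   \code{panel}, \code{meta}, \code{genotypes} and \code{pairs} (data
#'   frame \code{pair_id}, \code{case_id}, \code{control_id}).
#' @export
matched_cohort <- function(meta, genotypes, panel, age_tolerance = 5) {
  stopifnot(inherits(panel, "snp_panel"))
  req <- c("patient_id", "pair_id", "group", "sex", "age")
  if (!all(req %in% names(meta)))
    stop_("metadata must have columns: ", paste(req, collapse = ", "))
  meta$patient_id <- as.character(meta$patient_id)
  meta$pair_id <- as.character(meta$pair_id)
  meta$group <- tolower(as.character(meta$group))
  meta$sex <- toupper(as.character(meta$sex))
  if (anyDuplicated(meta$patient_id))
    stop_("duplicate patient_id: ",
          paste(unique(meta$patient_id[duplicated(meta$patient_id)]), collapse = ", "))
  if (!all(meta$group %in% c("case", "control")))
    stop_("group must be 'case' or 'control'")
  if (!all(meta$sex %in% c("M", "F"))) stop_("sex must be 'M' or 'F'")
  if (any(is.na(meta$age)) || any(meta$age <= 0)) stop_("age must be > 0")

  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)) || !setequal(rownames(genotypes), meta$patient_id))
    stop_("genotype rows must be named by the metadata patient_ids")
  genotypes <- genotypes[meta$patient_id, , drop = FALSE]
  unknown <- setdiff(colnames(genotypes), panel$rsid)
  if (length(unknown)) stop_("genotype columns not in panel: ",
                             paste(unknown, collapse = ", "))
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop_("alt-allele doses must be 0, 1, 2 or NA")

  pairs <- split(meta, meta$pair_id)
  bad_pairs <- character(0)
  out <- lapply(pairs, function(p) {
    ok <- nrow(p) == 2L && sum(p$group == "case") == 1L &&
      p$sex[1] == p$sex[2] && abs(diff(p$age)) <= age_tolerance
    if (!ok) return(NULL)
    data.frame(pair_id = p$pair_id[1],
               case_id = p$patient_id[p$group == "case"],
               control_id = p$patient_id[p$group == "control"],
               stringsAsFactors = FALSE)
  })
  bad_pairs <- names(pairs)[vapply(out, is.null, logical(1))]
  if (length(bad_pairs))
    stop_("invalid pair(s) (need one case + one control, same sex, |age diff| <= ",
          age_tolerance, "): ", paste(bad_pairs, collapse = ", "))
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL

  structure(list(panel = panel, meta = meta, genotypes = genotypes,
                 pairs = pairs),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched case-control cohort: %d patients in %d pairs, %d SNPs\n",
              nrow(x$meta), nrow(x$pairs), ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  overall genotype missingness: %.1f%%\n", 100 * miss))
  invisible(x)
}

# parse "X/Y" (or "X|Y") genotype strings against panel alleles;
# order-insensitive; returns integer alt dose with NA for missing/unparseable
parse_genotype_strings <- function(x, ref, alt) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  miss <- is.na(x) | x %in% c("", "NA", "./.", ".|.", ".")
  parts <- strsplit(x, "[/|]")
  ok <- !miss & lengths(parts) == 2L
  if (any(ok)) {
    a1 <- vapply(parts[ok], `[`, "", 1L)
    a2 <- vapply(parts[ok], `[`, "", 2L)
    valid <- a1 %in% c(ref, alt) & a2 %in% c(ref, alt)
    dose <- (a1 == alt) + (a2 == alt)
    dose[!valid] <- NA_integer_
    out[ok] <- as.integer(dose)
  }
  n_bad <- sum(!miss & is.na(out))
  attr(out, "n_unparseable") <- n_bad
  out
}

#' Read a matched cohort from genotype and metadata tables
#'
#' The metadata table is a TSV with header columns \code{patient_id},
#' \code{pair_id}, \code{group} (case/control), \code{sex} (M/F),
#' \code{age}, followed by optional numeric covariate columns. The genotype
#' table is a wide TSV: \code{patient_id} then one column per rsid holding
#' \code{"A/G"}-style calls (order-insensitive; \code{"NA"} or \code{"./."}
#' for missing). Calls using alleles outside the panel's ref/alt become
#' missing, with a warning giving the count.
#'
#' @param genotype_file,metadata_file file paths (TSV).
#' @param panel a \code{\link{snp_panel}}.
#' @param age_tolerance passed to \code{\link{matched_cohort}}.
#' @return A \code{\link{matched_cohort}}.
#' @export
read_cohort <- function(genotype_file, metadata_file, panel, age_tolerance = 5) {
  meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE,
                            check.names = FALSE,
                            colClasses = c(patient_id = "character",
                                           pair_id = "character",
                                           group = "character",
                                           sex = "character"))
  gt <- utils::read.delim(genotype_file, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (!"patient_id" %in% names(gt)) stop_("genotype table needs a patient_id column")
  if (!all(gt$patient_id %in% meta$patient_id))
    stop_("genotype table has patient_ids absent from metadata: ",
          paste(setdiff(gt$patient_id, meta$patient_id), collapse = ", "))
  rsids <- setdiff(names(gt), "patient_id")
  unknown <- setdiff(rsids, panel$rsid)
  if (length(unknown)) stop_("genotype columns not in panel: ",
                             paste(unknown, collapse = ", "))
  spec <- panel[match(rsids, panel$rsid), ]
  n_bad <- 0L
  mat <- vapply(seq_along(rsids), function(j) {
    d <- parse_genotype_strings(gt[[rsids[j]]], spec$ref[j], spec$alt[j])
    n_bad <<- n_bad + attr(d, "n_unparseable")
    as.integer(d)
  }, integer(nrow(gt)))
  mat <- matrix(mat, nrow = nrow(gt),
                dimnames = list(gt$patient_id, rsids))
  if (n_bad > 0)
    warn_(n_bad, " genotype call(s) used alleles outside the panel and were set to missing")
  matched_cohort(meta, mat, panel, age_tolerance = age_tolerance)
}

#' Write a matched cohort back to its tabular form
#'
#' Inverse of \code{\link{read_cohort}}: emits the metadata TSV and the wide
#' genotype TSV with \code{"X/Y"} calls reconstructed from alt-allele doses.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param genotype_file,metadata_file output paths.
#' @export
write_cohort <- function(cohort, genotype_file, metadata_file) {
  utils::write.table(cohort$meta, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- cohort$panel[match(colnames(cohort$genotypes), cohort$panel$rsid), ]
  gstr <- vapply(seq_len(ncol(cohort$genotypes)), function(j) {
    d <- cohort$genotypes[, j]
    out <- c(paste0(p$ref[j], "/", p$ref[j]),
             paste0(p$ref[j], "/", p$alt[j]),
             paste0(p$alt[j], "/", p$alt[j]))[d + 1L]
    out[is.na(d)] <- "NA"
    out
  }, character(nrow(cohort$genotypes)))
  gt <- data.frame(patient_id = rownames(cohort$genotypes),
                   matrix(gstr, nrow = nrow(cohort$genotypes)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(gt) <- c("patient_id", colnames(cohort$genotypes))
  utils::write.table(gt, genotype_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cohort)
}

#' Read genotype calls from a VCF file
#'
#' Reads biallelic SNP records with a GT field from a VCF v4.x file and
#' converts them to alternative-allele doses: \code{0/0} to 0, \code{0/1}
#' (or \code{1/0}, phased equivalents) to 1, \code{1/1} to 2, \code{./.} to
#' missing. Multi-allelic records are skipped with a warning.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param samples optional character vector restricting to these sample ids.
#' @return Integer matrix of doses, rows = rsid (the VCF ID column),
#'   columns = samples.
#' @export
read_vcf_genotypes <- function(path, samples = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_("package 'vcfR' is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = dimnames(vcfR::getFIX(v)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warn_("skipping ", sum(multi), " multi-allelic record(s): ",
          paste(fix[multi, "ID"], collapse = ", "))
  }
  fmt <- v@gt[, "FORMAT"]
  no_gt <- !vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))
  if (any(no_gt))
    stop_("record(s) without GT in FORMAT: ",
          paste(fix[no_gt, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) stop_("sample(s) not in VCF: ",
                                 paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  alleles <- gsub("[|/]", "", gt)
  dose <- nchar(gsub("0", "", alleles))
  dose[!grepl("^[01][|/][01]$", gt)] <- NA
  mode(dose) <- "integer"
  dimnames(dose) <- dimnames(gt)
  dose
}

check_rsid <- function(cohort, rsid) {
  if (!(rsid %in% cohort$panel$rsid)) stop_("unknown rsid: ", rsid)
  if (!(rsid %in% colnames(cohort$genotypes)))
    stop_("rsid not genotyped in this cohort: ", rsid)
}

#' Fraction of patients with a missing genotype at one SNP
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param rsid SNP identifier (must be in the panel).
#' @return Fraction in \[0, 1\].
#' @export
missingness <- function(cohort, rsid) {
  check_rsid(cohort, rsid)
  mean(is.na(cohort$genotypes[, rsid]))
}

#' Pairs with complete genotypes at one SNP
#'
#' Matched analyses delete pairwise: a pair enters the analysis of a SNP
#' only when both members have a non-missing call there. This returns the
#' retained pairs, the denominator set for all matched tests at that SNP.
#'
#' @inheritParams missingness
#' @return Data frame with columns \code{pair_id}, \code{case_id},
#'   \code{control_id} (subset of \code{cohort$pairs}).
#' @export
complete_pairs <- function(cohort, rsid) {
  check_rsid(cohort, rsid)
  g <- cohort$genotypes[, rsid]
  keep <- !is.na(g[cohort$pairs$case_id]) & !is.na(g[cohort$pairs$control_id])
  cohort$pairs[keep, , drop = FALSE]
}
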