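## Readers and writers: VCF genotypes (parsing delegated to vcfR), plain
## phenotype/weight tables, and result files (TSV/JSON).

#' Read biallelic SNP genotypes from a VCF
#'
#' Loads the GT field of a VCF (plain or gzipped) and converts each usable
#' record into a genotype site. A record is usable when it is a biallelic
#' SNP (single-base REF and ALT, no comma in ALT), has parseable diploid GT
#' calls, and is not monomorphic in the sample. Skipped records are counted
#' by reason and the tally is reported via a message and returned.
#'
#' @param path Path to a VCF file (`.vcf` or `.vcf.gz`).
#' @param region Optional region filter, `"chrom"` or `"chrom:start-end"`
#'   (1-based inclusive, as in VCF).
#' @param missing Policy for missing calls (`./.`, half-calls, `.`):
#'   `"error"` (default) aborts naming site and individual, `"drop_site"`
#'   skips the record and counts it, `"ref_impute"` treats them as `0/0`.
#' @return A list with `individual_ids` (sample names in VCF order),
#'   `sites` (a `gvd_sites` tibble in record order) and `log` (a one-row
#'   tibble of record counts by fate).
#' @export
read_vcf <- function(path, region = NULL,
                     missing = c("error", "drop_site", "ref_impute")) {
  missing <- match.arg(missing)
  if (!file.exists(path)) abort(sprintf("cannot read VCF: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) abort("no usable sites in VCF.")
  ids <- colnames(vcf@gt)[-1L]
  gt <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE,
                     IDtoRowNames = FALSE)
  )

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1L]]
    if (length(m) == 0L) abort("`region` must be \"chrom\" or \"chrom:start-end\".")
    keep <- fix[, "CHROM"] == m[2L]
    if (nzchar(m[3L])) {
      pos <- as.integer(fix[, "POS"])
      keep <- keep & pos >= as.integer(m[3L]) & pos <= as.integer(m[4L])
    }
  }

  counts <- c(records = nrow(fix), used = 0L, outside_region = sum(!keep),
              multiallelic = 0L, non_snp = 0L, no_gt = 0L,
              invalid_call = 0L, missing_dropped = 0L, monomorphic = 0L)
  sites <- list()
  bases <- c("A", "C", "G", "T")
  for (k in which(keep)) {
    ref <- fix[k, "REF"]; alt <- fix[k, "ALT"]
    chrom <- fix[k, "CHROM"]; pos <- fix[k, "POS"]
    rsid <- fix[k, "ID"]
    if (is.na(alt) || grepl(",", alt, fixed = TRUE)) {
      counts["multiallelic"] <- counts["multiallelic"] + 1L
      next
    }
    if (!(toupper(ref) %in% bases) || !(toupper(alt) %in% bases)) {
      counts["non_snp"] <- counts["non_snp"] + 1L
      next
    }
    calls <- as.character(gt[k, ])
    if (all(is.na(calls))) {
      counts["no_gt"] <- counts["no_gt"] + 1L
      next
    }
    calls[is.na(calls)] <- "./."
    pc <- parse_calls(calls)
    if (any(pc$invalid)) {
      counts["invalid_call"] <- counts["invalid_call"] + 1L
      next
    }
    if (any(pc$missing)) {
      if (missing == "error") {
        bad <- which(pc$missing)[1L]
        abort(sprintf(
          "missing genotype for individual %s at %s:%s (policy \"error\").",
          ids[bad], chrom, pos
        ))
      } else if (missing == "drop_site") {
        counts["missing_dropped"] <- counts["missing_dropped"] + 1L
        next
      } else {
        calls[pc$missing] <- "0/0"
      }
    }
    site <- genotype_site(calls, chrom = chrom, pos = as.integer(pos),
                          rsid = if (is.na(rsid) || rsid == ".") NA_character_ else rsid)
    if (is_monomorphic(site)) {
      counts["monomorphic"] <- counts["monomorphic"] + 1L
      next
    }
    counts["used"] <- counts["used"] + 1L
    sites[[length(sites) + 1L]] <- site
  }
  if (counts["used"] == 0L) abort("no usable sites in VCF.")
  sites <- dplyr::bind_rows(sites)
  class(sites) <- c("gvd_sites", setdiff(class(sites), "gvd_sites"))
  inform(sprintf(
    "VCF %s: %d record(s); used %d; skipped %d multiallelic, %d non-SNP, %d without GT, %d unparseable, %d with missing calls, %d monomorphic%s.",
    basename(path), counts["records"], counts["used"], counts["multiallelic"],
    counts["non_snp"], counts["no_gt"], counts["invalid_call"],
    counts["missing_dropped"], counts["monomorphic"],
    if (!is.null(region)) sprintf(", %d outside region", counts["outside_region"]) else ""
  ))
  list(individual_ids = ids, sites = sites,
       log = as_tibble(as.list(counts)))
}

#' Read a phenotype table
#'
#' Reads trait values from a 2-column whitespace/tab-separated file
#' (individual ID, value) or a 1-column value file already in VCF sample
#' order, reorders them to `individual_ids`, and centers them.
#'
#' @param path Path to the phenotype file. An optional header line is
#'   tolerated in the 2-column form.
#' @param individual_ids Sample IDs, in the order the genotypes use.
#' @return A centered `gvd_phenotype` vector named by `individual_ids`.
#' @export
read_phenotype <- function(path, individual_ids) {
  if (!file.exists(path)) abort(sprintf("cannot read phenotype file: %s", path))
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "#")
  if (!ncol(df) %in% c(1L, 2L)) {
    abort("phenotype file must have 1 (value) or 2 (id, value) columns.")
  }
  if (ncol(df) == 2L) {
    # tolerate a header row such as "id  value"
    if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1L, 2L]))) &&
        !(df[1L, 1L] %in% individual_ids)) {
      df <- df[-1L, , drop = FALSE]
    }
    if (anyDuplicated(df[[1L]])) {
      abort(sprintf("duplicate individual \"%s\" in phenotype file.",
                    df[[1L]][duplicated(df[[1L]])][1L]))
    }
    idx <- match(individual_ids, df[[1L]])
    if (anyNA(idx)) {
      abort(sprintf("phenotype file is missing individual \"%s\".",
                    individual_ids[which(is.na(idx))[1L]]))
    }
    vals_chr <- df[[2L]][idx]
    labels <- individual_ids
  } else {
    if (nrow(df) != length(individual_ids)) {
      abort(sprintf(
        "1-column phenotype file has %d values for %d individuals.",
        nrow(df), length(individual_ids)
      ))
    }
    vals_chr <- df[[1L]]
    labels <- individual_ids
  }
  vals <- suppressWarnings(as.numeric(vals_chr))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    abort(sprintf("non-numeric phenotype value \"%s\" for individual \"%s\".",
                  vals_chr[bad], labels[bad]))
  }
  names(vals) <- individual_ids
  center_phenotype(vals)
}

#' Read a per-site weight table
#'
#' Reads a 2-column file (site key, weight), where the key is either
#' `chrom:pos` or the rsID, and resolves one weight for every site. Any
#' site without a matching weight is an error: silently dropping weights
#' would corrupt the aggregate statistic.
#'
#' @param path Path to the weight file.
#' @param sites A `gvd_sites` tibble.
#' @return A custom [weight_scheme()] with one weight per site, in site order.
#' @export
read_weights <- function(path, sites) {
  check_sites(sites)
  if (!file.exists(path)) abort(sprintf("cannot read weight file: %s", path))
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "#")
  if (ncol(df) != 2L) abort("weight file must have 2 columns: key, weight.")
  w <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(w)) {
    abort(sprintf("non-numeric weight \"%s\" for key \"%s\".",
                  df[[2L]][which(is.na(w))[1L]], df[[1L]][which(is.na(w))[1L]]))
  }
  key_pos <- paste0(sites$chrom, ":", sites$pos)
  idx <- match(key_pos, df[[1L]])
  miss <- is.na(idx) & !is.na(sites$rsid)
  idx[miss] <- match(sites$rsid[miss], df[[1L]])
  if (anyNA(idx)) {
    abort(sprintf("no weight found for site %s.", key_pos[which(is.na(idx))[1L]]))
  }
  weight_scheme("custom", weights = w[idx])
}

#' Write simulated genotypes as a minimal VCF
#'
#' Emits a VCF 4.2 file carrying only the GT field, so simulated data can
#' exercise the same file path as real data. REF/ALT are placeholder
#' bases (`A`/`C`).
#'
#' @param sites A `gvd_sites` tibble.
#' @param individual_ids Sample IDs (default `ind1..indn`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path,
                      individual_ids = paste0("ind", seq_len(sites$n[1L]))) {
  check_sites(sites)
  if (nrow(sites) == 0L) abort("`sites` is empty; nothing to write.")
  if (length(individual_ids) != sites$n[1L]) {
    abort("`individual_ids` length must equal the sample size.")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gvdtest",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individual_ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(sites)), function(k) {
    calls <- c("0/0", "0/1", "1/1")[sites$g[[k]] + 1L]
    paste(c(sites$chrom[k], sites$pos[k],
            if (is.na(sites$rsid[k])) "." else sites$rsid[k],
            "A", "C", ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a phenotype table
#'
#' Two tab-separated columns (individual ID, value), no header, full
#' precision — the format [read_phenotype()] reads back.
#'
#' @param values Numeric trait values.
#' @param path Output path.
#' @param individual_ids Sample IDs (default `ind1..indn`).
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(values, path,
                            individual_ids = paste0("ind", seq_along(values))) {
  if (length(values) != length(individual_ids)) {
    abort("`values` and `individual_ids` lengths differ.")
  }
  writeLines(paste(individual_ids, format(values, digits = 17, trim = TRUE,
                                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

result_record <- function(result) {
  if (inherits(result, "gvd_kernel")) {
    list(type = "kernel_statistic", kernel = result$kernel, S = result$S,
         n = result$n, n_sites = result$n_sites,
         weights = as.numeric(result$weights),
         per_site = result$per_site)
  } else if (inherits(result, "gvd_perm")) {
    list(type = "permutation_test", kernel = result$kernel,
         S = result$observed_S, B = result$B, count_ge = result$count_ge,
         p_value = result$p_value, seed = result$seed, n = result$n,
         n_sites = result$n_sites)
  } else if (inherits(result, "gvd_power")) {
    as.list(glance(result))
  } else {
    abort("`result` must be a gvd_kernel, gvd_perm or gvd_power object.")
  }
}

#' Write a result file
#'
#' Serializes a kernel-statistic, permutation-test or power-experiment
#' result as JSON (round-trippable, all seeds and parameters included) or
#' as a single-row TSV with a header naming every column. Numeric values
#' keep at least 10 significant digits.
#'
#' @param result A `gvd_kernel`, `gvd_perm` or `gvd_power` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (default guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  rec <- result_record(result)
  if (format == "json") {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, dataframe = "columns")
  } else {
    flat <- rec[!vapply(rec, is.data.frame, logical(1))]
    flat <- lapply(flat, function(v) {
      if (is.numeric(v)) paste(format(v, digits = 15, trim = TRUE), collapse = ",")
      else paste(v, collapse = ",")
    })
    df <- as.data.frame(flat, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  invisible(path)
}
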