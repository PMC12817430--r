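#' Write a genotype matrix as VCF v4.2
#'
#' Emits diploid `GT` (plus `DP` when per-genotype depth is present),
#' per-site numeric INFO fields for every site-annotation column, and
#' contig header lines. Positions are 1-based. The dosage/locus/id part
#' of the file round-trips exactly through [read_vcf()]; numeric
#' annotations are written with 9 significant digits.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  ann <- G$site_annotations
  hdr <- c("##fileformat=VCFv4.2",
           "##source=seedtrace",
           sprintf("##contig=<ID=%s>", unique(G$loci$chrom)),
           if (!is.null(ann))
             sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Site annotation %s\">",
                     names(ann), names(ann)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (!is.null(G$depth))
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$individual_ids), collapse = "\t"))
  j <- n_loci(G)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- character(0)
  if (j > 0) {
    info <- if (is.null(ann)) rep(".", j) else {
      cols <- lapply(names(ann), function(nm)
        paste0(nm, "=", sprintf("%.9g", ann[[nm]])))
      do.call(paste, c(cols, sep = ";"))
    }
    gt <- matrix(gt_codes[G$dosages + 1L], nrow(G$dosages))
    gt[is.na(G$dosages)] <- "./."
    if (!is.null(G$depth)) {
      dp <- matrix(as.character(G$depth), nrow(G$depth))
      dp[is.na(G$depth)] <- "."
      gt <- matrix(paste(gt, dp, sep = ":"), nrow(gt))
      fmt <- "GT:DP"
    } else fmt <- "GT"
    sample_cols <- apply(gt, 2, paste, collapse = "\t")
    body <- paste(G$loci$chrom, G$loci$pos, ".", G$loci$ref, G$loci$alt,
                  ".", ".", info, fmt, sample_cols, sep = "\t")
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) .stopf("I/O error: cannot open %s", path))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Accepts VCF v4.x with a `GT` FORMAT field. Multi-allelic records and
#' non-SNP records (indels, symbolic alleles) are excluded with a
#' logged count. `./.` genotypes map to missing dosage; numeric INFO
#' key=value fields become site annotations; `DP` per-genotype depth is
#' kept when present.
#'
#' @param path VCF file path.
#' @param quiet suppress the exclusion message.
#' @return a [genotype_matrix()]. The number of excluded records is
#'   attached as attribute `excluded`.
#' @export
read_vcf <- function(path, quiet = FALSE) {
  if (!file.exists(path)) .stopf("I/O error: no such file %s", path)
  lines <- readLines(path)
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1)
    .stopf("malformed VCF %s: missing #CHROM header line", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) .stopf("malformed VCF %s: no sample columns", path)
  samples <- hdr[-(1:9)]
  body_idx <- seq.int(hdr_i + 1L, length.out = length(lines) - hdr_i)
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(genotype_matrix(matrix(NA_integer_, length(samples), 0),
                           samples,
                           data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(hdr))) {
    bad <- which(nf != length(hdr))[1]
    .stopf("malformed VCF %s: line %d has %d fields, expected %d",
           path, hdr_i + bad, nf[bad], length(hdr))
  }
  m <- matrix(unlist(parts), ncol = length(hdr), byrow = TRUE)
  ref <- m[, 4]; alt <- m[, 5]
  keep <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  excluded <- sum(!keep)
  if (excluded && !quiet)
    message(sprintf("read_vcf: excluded %d multi-allelic/non-SNP record(s)", excluded))
  m <- m[keep, , drop = FALSE]
  j <- nrow(m); n <- length(samples)

  fmt <- strsplit(m[, 9], ":", fixed = TRUE)
  gt_pos <- vapply(fmt, function(f) match("GT", f), 0L)
  if (anyNA(gt_pos)) {
    bad <- which(is.na(gt_pos))[1]
    .stopf("malformed VCF %s: record %d lacks GT in FORMAT", path, bad)
  }
  dp_pos <- vapply(fmt, function(f) match("DP", f, nomatch = 0L), 0L)

  calls <- m[, -(1:9), drop = FALSE]              # j x n
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos <- matrix(NA_integer_, n, j)
  dep <- if (any(dp_pos > 0)) matrix(NA_integer_, n, j) else NULL
  for (r in seq_len(j)) {
    f <- strsplit(calls[r, ], ":", fixed = TRUE)
    gts <- vapply(f, `[`, "", gt_pos[r])
    dos[, r] <- gt_map[gts]
    if (!is.null(dep) && dp_pos[r] > 0) {
      dv <- vapply(f, function(x) if (length(x) >= dp_pos[r]) x[dp_pos[r]] else ".", "")
      dep[, r] <- suppressWarnings(as.integer(dv))
    }
  }

  ann <- .parse_info(m[, 8])
  genotype_matrix(dos, samples,
                  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                             ref = ref[keep], alt = alt[keep],
                             stringsAsFactors = FALSE),
                  site_annotations = ann, depth = dep) |>
    structure(excluded = excluded)
}

# numeric key=value INFO fields -> data.frame (non-numeric keys dropped)
.parse_info <- function(info) {
  if (all(info == ".")) return(NULL)
  kv <- strsplit(info, ";", fixed = TRUE)
  with_eq <- unlist(lapply(kv, function(x) x[grepl("=", x, fixed = TRUE)]))
  keys <- unique(sub("=.*", "", with_eq))
  if (!length(keys)) return(NULL)
  out <- lapply(keys, function(k) {
    pre <- paste0(k, "=")
    vapply(kv, function(x) {
      hit <- x[startsWith(x, pre)]
      if (length(hit)) suppressWarnings(as.numeric(sub(pre, "", hit[1], fixed = TRUE)))
      else NA_real_
    }, 0)
  })
  names(out) <- keys
  out <- out[vapply(out, function(x) any(is.finite(x)), TRUE)]
  if (!length(out)) return(NULL)
  as.data.frame(out)
}
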