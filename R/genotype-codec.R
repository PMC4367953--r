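# Packed genotype storage and PLINK text PED/MAP input/output.
#
# Genotypes are minor-allele dosages {0,1,2} plus a missing state, held as
# three packed bitplanes per individual: (g >= 1), (g == 2) and a missingness
# mask. The unary two-bit code makes the absolute dosage difference between
# two individuals a pure Hamming weight, which is what the IBS kernel counts.

#' Pack a genotype code matrix into 2-bit storage
#'
#' @param codes integer matrix, individuals in rows and SNPs in columns, with
#'   entries in `{0, 1, 2}` or missing (`NA` or `missing_code`).
#' @param snp_ids,individual_ids optional identifier vectors; defaults are
#'   generated.
#' @param alleles optional data frame with columns `a1`, `a2` giving the
#'   reference and coded (minor) allele letter per SNP, used by
#'   [write_ped_map()].
#' @param missing_code additional sentinel treated as missing (e.g. `-9`).
#' @return an object of class `packed_genotypes`.
#' @examples
#' pg <- pack_genotypes(matrix(c(0L, 1L, 2L, NA, 0L, 2L), nrow = 2))
#' unpack_genotypes(pg)
#' @export
pack_genotypes <- function(codes, snp_ids = NULL, individual_ids = NULL,
                           alleles = NULL, missing_code = NA_integer_) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!is.na(missing_code)) codes[codes == missing_code] <- NA_integer_
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) {
    stop("invalid genotype code(s): ",
         paste(unique(codes[bad]), collapse = ", "),
         "; allowed codes are 0, 1, 2 and missing")
  }
  n <- nrow(codes)
  s <- ncol(codes)
  if (is.null(snp_ids)) snp_ids <- if (!is.null(colnames(codes))) colnames(codes) else sprintf("snp%d", seq_len(s))
  if (is.null(individual_ids)) individual_ids <- if (!is.null(rownames(codes))) rownames(codes) else sprintf("ind%d", seq_len(n))
  stopifnot(length(snp_ids) == s, length(individual_ids) == n)

  s_pad <- 8L * as.integer(ceiling(s / 8))
  pad <- function(plane, fill) {
    # loci-major per individual, padded to full bytes
    m <- matrix(fill, nrow = s_pad, ncol = n)
    if (s > 0) m[seq_len(s), ] <- t(plane)
    packBits(as.vector(m), type = "raw")
  }
  miss <- is.na(codes)
  pg <- list(
    p1 = pad(!miss & codes >= 1L, FALSE),
    p2 = pad(!miss & codes == 2L, FALSE),
    mm = pad(miss, TRUE),             # padding bits flagged missing
    n_individuals = n,
    n_snps = s,
    bytes_per_ind = s_pad %/% 8L,
    snp_ids = as.character(snp_ids),
    individual_ids = as.character(individual_ids),
    alleles = alleles
  )
  class(pg) <- "packed_genotypes"
  pg
}

#' Unpack 2-bit genotypes back to an integer code matrix
#'
#' Inverse of [pack_genotypes()]; the round trip is the identity.
#'
#' @param pg a `packed_genotypes` object.
#' @return integer matrix (individuals x SNPs) with `NA` for missing.
#' @export
unpack_genotypes <- function(pg) {
  stopifnot(inherits(pg, "packed_genotypes"))
  n <- pg$n_individuals
  s <- pg$n_snps
  s_pad <- pg$bytes_per_ind * 8L
  take <- function(r) {
    m <- matrix(as.logical(rawToBits(r)), nrow = s_pad, ncol = n)
    t(m[seq_len(max(s, 0L)), , drop = FALSE])
  }
  if (s == 0L || n == 0L) {
    out <- matrix(NA_integer_, n, s)
  } else {
    out <- take(pg$p1) + take(pg$p2)
    out[take(pg$mm)] <- NA_integer_
    storage.mode(out) <- "integer"
  }
  dimnames(out) <- list(pg$individual_ids, pg$snp_ids)
  out
}

#' @export
as.matrix.packed_genotypes <- function(x, ...) unpack_genotypes(x)

#' @export
dim.packed_genotypes <- function(x) c(x$n_individuals, x$n_snps)

#' @export
print.packed_genotypes <- function(x, ...) {
  cat(sprintf("packed_genotypes: %d individuals x %d SNPs (%.1f kB packed)\n",
              x$n_individuals, x$n_snps,
              3 * length(x$p1) / 1024))
  invisible(x)
}

.geno_matrix <- function(x) {
  if (inherits(x, "packed_genotypes")) unpack_genotypes(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "integer"
    m
  }
}

#' Case-control phenotype
#'
#' @param status vector of affection states: integer `0` (control) / `1`
#'   (case), or character/factor `"control"`/`"case"`; `NA` = missing.
#' @param ids optional individual identifiers.
#' @return object of class `phenotype` with fields `status` and `ids`.
#' @examples
#' ph <- phenotype(c(0, 1, 1, NA))
#' cases(ph); controls(ph)
#' @export
phenotype <- function(status, ids = NULL) {
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status)
    ok <- status %in% c("control", "case") | is.na(status)
    if (!all(ok)) stop("character status must be 'control' or 'case'")
    status <- ifelse(status == "case", 1L, 0L)
  }
  status <- as.integer(status)
  if (any(!is.na(status) & !(status %in% 0:1))) stop("status must be 0 (control), 1 (case) or NA")
  if (is.null(ids)) ids <- sprintf("ind%d", seq_along(status))
  structure(list(status = status, ids = as.character(ids)), class = "phenotype")
}

#' @rdname phenotype
#' @param phen a `phenotype` object.
#' @return `cases()`/`controls()`: integer index sets (disjoint, covering all
#'   phenotyped individuals).
#' @export
cases <- function(phen) which(!is.na(phen$status) & phen$status == 1L)

#' @rdname phenotype
#' @export
controls <- function(phen) which(!is.na(phen$status) & phen$status == 0L)

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("phenotype: %d individuals (%d controls, %d cases, %d missing)\n",
              length(x$status), length(controls(x)), length(cases(x)),
              sum(is.na(x$status))))
  invisible(x)
}

.open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read PLINK text PED/MAP files
#'
#' Genotypes are recoded as minor-allele dosages per SNP. The minor allele is
#' determined from the loaded sample; when both alleles are equally frequent
#' the lexicographically larger letter is taken as the coded (minor) allele.
#' PED phenotype column: 1 = control, 2 = case; anything else is treated as a
#' missing phenotype and the individual is excluded from the case/control
#' sets, with a warning.
#'
#' @param ped_path,map_path paths to whitespace-delimited PED and MAP files
#'   (optionally gzip-compressed).
#' @return list with components `genotypes` ([pack_genotypes()] object) and
#'   `phenotype` ([phenotype()] object).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 3) stop("MAP file must have at least 3 columns")
  snp_ids <- as.character(map[[2]])
  s <- nrow(map)

  con <- .open_text(ped_path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(toks)
  if (length(unique(nfield)) > 1) stop("ragged PED file: unequal field counts across lines")
  if (length(toks) > 0 && nfield[1] != 6 + 2 * s) {
    stop(sprintf("PED/MAP mismatch: PED has %d fields per line, expected %d (6 + 2 x %d SNPs)",
                 nfield[1], 6 + 2 * s, s))
  }
  n <- length(toks)
  tk <- matrix(unlist(toks), nrow = n, byrow = TRUE)

  ids <- tk[, 2]
  if (anyDuplicated(ids)) ids <- paste(tk[, 1], tk[, 2], sep = "_")
  ph_raw <- tk[, 6]
  status <- rep(NA_integer_, n)
  status[ph_raw == "1"] <- 0L
  status[ph_raw == "2"] <- 1L
  n_bad <- sum(is.na(status))
  if (n_bad > 0) {
    warning(sprintf("%d individual(s) with unrecognised phenotype code excluded from case/control sets", n_bad))
  }

  codes <- matrix(NA_integer_, n, s)
  a1vec <- character(s)
  a2vec <- character(s)
  for (k in seq_len(s)) {
    al1 <- tk[, 5 + 2 * k]
    al2 <- tk[, 6 + 2 * k]
    both <- c(al1, al2)
    seen <- sort(unique(both[both != "0"]))
    if (length(seen) > 2) {
      stop(sprintf("SNP '%s' is not biallelic (alleles: %s)", snp_ids[k], paste(seen, collapse = ",")))
    }
    if (length(seen) == 0) {
      a1vec[k] <- "0"; a2vec[k] <- "0"
      next
    }
    cnt <- vapply(seen, function(a) sum(both == a), integer(1))
    if (length(seen) == 1) {
      minor <- NA_character_; major <- seen[1]
    } else if (cnt[1] < cnt[2]) {
      minor <- seen[1]; major <- seen[2]
    } else if (cnt[2] < cnt[1]) {
      minor <- seen[2]; major <- seen[1]
    } else {
      minor <- seen[2]; major <- seen[1]   # tie: lexicographically larger is minor
    }
    miss <- al1 == "0" | al2 == "0"
    if (is.na(minor)) {
      codes[!miss, k] <- 0L
      a1vec[k] <- major; a2vec[k] <- "0"
    } else {
      codes[, k] <- (al1 == minor) + (al2 == minor)
      codes[miss, k] <- NA_integer_
      a1vec[k] <- major; a2vec[k] <- minor
    }
  }
  pg <- pack_genotypes(codes, snp_ids = snp_ids, individual_ids = ids,
                       alleles = data.frame(a1 = a1vec, a2 = a2vec,
                                            stringsAsFactors = FALSE))
  list(genotypes = pg, phenotype = phenotype(status, ids = ids))
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()] up to allele-letter relabeling: dosage codes
#' are written using the stored allele letters (`a2` = coded allele), or
#' `A`/`B` when none are stored. Reading the files back recodes against the
#' sample minor allele, so orientation is preserved whenever the coded allele
#' is no more frequent than the reference allele.
#'
#' @param pg a `packed_genotypes` object.
#' @param phen a `phenotype` object (written as 1 = control, 2 = case,
#'   0 = missing).
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(pg, phen, ped_path, map_path) {
  codes <- .geno_matrix(pg)
  n <- nrow(codes); s <- ncol(codes)
  al <- pg$alleles
  if (is.null(al)) al <- data.frame(a1 = rep("A", s), a2 = rep("B", s), stringsAsFactors = FALSE)
  map <- data.frame(chr = 1L, id = pg$snp_ids, cm = 0L, pos = seq_len(max(s, 1L))[seq_len(s)])
  write.table(map, map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)

  ph <- ifelse(is.na(phen$status), 0L, phen$status + 1L)
  lines <- character(n)
  for (i in seq_len(n)) {
    gl <- character(2 * s)
    for (k in seq_len(s)) {
      g <- codes[i, k]
      a <- if (is.na(g)) c("0", "0")
           else switch(g + 1L, c(al$a1[k], al$a1[k]), c(al$a1[k], al$a2[k]), c(al$a2[k], al$a2[k]))
      gl[c(2 * k - 1, 2 * k)] <- a
    }
    lines[i] <- paste(c(pg$individual_ids[i], pg$individual_ids[i], "0", "0", "0", ph[i], gl),
                      collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
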