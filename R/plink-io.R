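#' Read PLINK binary genotype files
#'
#' Reads a `.bed`/`.bim`/`.fam` triple in SNP-major mode into a
#' [genotype_dataset()].  Dosages count the BIM allele-1 (A1) allele.
#' The two-bit codes are decoded as 00 = two copies of allele 1,
#' 10 = one copy (heterozygote), 11 = zero copies, 01 = missing, with
#' the first sample of each byte in the lowest-order bit pair.
#'
#' @param prefix path stem; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must exist.
#' @return a [genotype_dataset()].  Sample order follows the FAM file,
#'   variant order the BIM file.
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing PLINK file(s): ", paste(missing, collapse = ", "))
  }

  fam <- read_fam(paths[3])
  bim <- read_bim(paths[2])
  n <- nrow(fam)
  m <- nrow(bim)

  con <- file(paths[1], "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 3)
  if (length(header) < 3 || header[1] != as.raw(0x6c) ||
      header[2] != as.raw(0x1b)) {
    stop("not a PLINK BED file (bad magic bytes): ", paths[1])
  }
  if (header[3] == as.raw(0x00)) {
    stop("individual-major BED files are not supported; ",
         "re-export in SNP-major mode")
  }
  if (header[3] != as.raw(0x01)) {
    stop("unknown BED mode byte: ", as.integer(header[3]))
  }

  bpv <- ceiling(n / 4)            # bytes per variant
  body <- readBin(con, "raw", n = bpv * m + 1L)
  if (length(body) != bpv * m) {
    stop("BED file has wrong length: expected ", bpv * m,
         " data bytes for ", n, " samples x ", m, " variants")
  }

  dosages <- decode_bed_bytes(body, n, m)
  genotype_dataset(dosages, fam, bim)
}

# Decode a raw vector of packed BED bytes (bpv bytes per variant,
# variants consecutive) into an n x m integer dosage matrix.
decode_bed_bytes <- function(body, n, m) {
  bpv <- ceiling(n / 4)
  if (m == 0L || n == 0L) {
    return(matrix(NA_integer_, nrow = n, ncol = m))
  }
  # 256 x 4 lookup: dosage of each 2-bit slot for every byte value.
  codes <- bed_code_table()
  ints <- as.integer(body)
  slots <- codes[ints + 1L, , drop = FALSE]       # (bpv*m) x 4, byte order
  arr <- array(t(slots), dim = c(4L, bpv, m))     # slot, byte, variant
  full <- matrix(arr, nrow = 4L * bpv, ncol = m)
  full[seq_len(n), , drop = FALSE]
}

# dosage per 2-bit code: 00 -> 2, 01 -> NA (missing), 10 -> 1, 11 -> 0
bed_code_table <- function() {
  code2dos <- c(2L, NA_integer_, 1L, 0L)
  b <- 0:255
  cbind(
    code2dos[bitwAnd(b, 3L) + 1L],
    code2dos[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
    code2dos[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
    code2dos[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L]
  )
}

#' Write PLINK binary genotype files
#'
#' Writes `<prefix>.bed` (SNP-major), `<prefix>.bim` and `<prefix>.fam`.
#' `read_plink(write_plink(x, prefix))` restores the dataset exactly,
#' including missing genotypes.
#'
#' @param x a [genotype_dataset()].
#' @param prefix output path stem; the directory must exist.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(x, prefix) {
  validate_genotype_dataset(x)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)

  write_fam(x$samples, paste0(prefix, ".fam"))
  write_bim(x$variants, paste0(prefix, ".bim"))

  n <- n_samples(x)
  m <- n_variants(x)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    writeBin(encode_bed_bytes(x$dosages), con)
  }
  invisible(prefix)
}

# Pack an n x m dosage matrix into raw BED bytes (SNP-major).
encode_bed_bytes <- function(dosages) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  bpv <- ceiling(n / 4)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  dos2code <- c(3L, 2L, 0L)
  codes <- matrix(dos2code[dosages + 1L], nrow = n)
  codes[is.na(codes)] <- 1L
  pad <- matrix(0L, nrow = 4L * bpv - n, ncol = m)
  codes <- rbind(codes, pad)
  arr <- array(codes, dim = c(4L, bpv, m))
  bytes <- arr[1, , , drop = TRUE] + 4L * arr[2, , , drop = TRUE] +
    16L * arr[3, , , drop = TRUE] + 64L * arr[4, , , drop = TRUE]
  as.raw(bytes)
}

read_fam <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(family_id = character(), individual_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = integer(), phenotype = numeric(),
                      stringsAsFactors = FALSE))
  }
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c(rep("character", 4), "integer",
                                          "numeric"))
  names(fam) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  fam
}

write_fam <- function(samples, path) {
  pheno <- samples$phenotype
  if (is.null(pheno)) pheno <- rep(-9, nrow(samples))
  out <- data.frame(samples$family_id, samples$individual_id,
                    samples$father_id, samples$mother_id, samples$sex,
                    pheno)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

read_bim <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chromosome = integer(), id = character(),
                      cm = numeric(), position = integer(),
                      allele1 = character(), allele2 = character(),
                      stringsAsFactors = FALSE))
  }
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character",
                                          "character"))
  names(bim) <- c("chromosome", "id", "cm", "position", "allele1",
                  "allele2")
  bim
}

write_bim <- function(variants, path) {
  cm <- variants$cm
  if (is.null(cm)) cm <- rep(0, nrow(variants))
  out <- data.frame(variants$chromosome, variants$id, cm,
                    variants$position, variants$allele1, variants$allele2)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
}

#' Read and write cluster assignment tables
#'
#' Tab-delimited files with header columns `family_id`, `individual_id`,
#' `group`, `outlier`, `node_path`; one row per sample.
#'
#' @param assignment data frame as produced by [ipclust()] (component
#'   `assignment`).
#' @param path file path.
#' @return `read_assignment` returns the assignment data frame;
#'   `write_assignment` returns `path` invisibly.
#' @export
write_assignment <- function(assignment, path) {
  need <- c("family_id", "individual_id", "group", "outlier", "node_path")
  if (!all(need %in% names(assignment))) {
    stop("assignment must have columns: ", paste(need, collapse = ", "))
  }
  utils::write.table(assignment[, need], path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "logical",
                                          "character"))
  key <- paste(tab$family_id, tab$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate sample rows in assignment file: ",
         paste(tab$individual_id[duplicated(key)], collapse = ", "))
  }
  tab
}
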