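# Header comment written at the top of every TSV this package emits:
# tool version, seed and md5 of the inputs it was derived from.
file_header <- function(seed = NA, input_files = character(0)) {
  ver <- as.character(utils::packageVersion("kinpred"))
  hashes <- if (length(input_files)) {
    h <- tools::md5sum(input_files)
    paste(sprintf("%s=%s", basename(names(h)), unname(h)), collapse = ",")
  } else "none"
  sprintf("# kinpred %s | seed=%s | inputs=%s", ver, as.character(seed), hashes)
}

write_tsv_commented <- function(tbl, path, seed = NA,
                                input_files = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(seed, input_files), con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK1 bed/bim/fam
#'
#' Variant-major PLINK1 binary. The stored dosage counts the A1 (alternate)
#' allele, so the two-bit codes are: `00` = homozygous A1 (dosage 2),
#' `01` = missing, `10` = heterozygous, `11` = homozygous A2 (dosage 0);
#' four individuals per byte, first individual in the lowest-order bits.
#' The bim file uses chromosome 1 with consecutive integer positions.
#'
#' @param genotypes A [geno_matrix()].
#' @param prefix Path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam`.
#' @param pedigree Optional pedigree supplying family ids and sexes for the
#'   fam file.
#' @return Invisibly, the bed path.
#' @export
write_plink <- function(genotypes, prefix, pedigree = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  n <- nrow(d)
  m <- ncol(d)
  # two-bit codes: dosage 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  codes <- matrix(3L, n, m)
  codes[d == 2L] <- 0L
  codes[is.na(d)] <- 1L
  codes[d == 1L] <- 2L
  n_pad <- ceiling(n / 4) * 4
  if (n_pad > n) codes <- rbind(codes, matrix(0L, n_pad - n, m))
  # pack 4 individuals per byte, individual 1 in bits 0-1
  i1 <- seq(1, n_pad, by = 4)
  bytes <- codes[i1, , drop = FALSE] +
    4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] +
    64L * codes[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) writeBin(as.raw(bytes), con)  # column-major = variant-major
  close(con)
  bim <- data.frame(chr = rep(1L, m), snp = genotypes$snp_ids, cm = rep(0, m),
                    pos = seq_len(m), a1 = rep("A", m), a2 = rep("G", m))
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- genotypes$ids
  if (!is.null(pedigree)) {
    fam_id <- stats::setNames(pedigree$family_id, pedigree$id)[ids]
    sex <- stats::setNames(pedigree$sex, pedigree$id)[ids]
    sex_code <- ifelse(is.na(sex), 0L, ifelse(sex == "M", 1L, 2L))
    fam_id[is.na(fam_id)] <- ids[is.na(fam_id)]
  } else {
    fam_id <- ids
    sex_code <- 0L
  }
  fam <- data.frame(fid = fam_id, iid = ids, pid = 0L, mid = 0L,
                    sex = sex_code, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, ".bed"))
}

#' Read PLINK1 bed/bim/fam genotypes
#'
#' Counterpart of [write_plink()]; accepts any variant-major PLINK1 fileset.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triple.
#' @return A [geno_matrix()] (dosage = A1 allele count, missing preserved).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  bim_path <- paste0(prefix, ".bim")
  bim_info <- file.info(bim_path)
  bim <- if (!is.na(bim_info$size) && bim_info$size > 0) {
    utils::read.table(bim_path, stringsAsFactors = FALSE)
  } else {
    data.frame(V1 = integer(0), V2 = character(0))
  }
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK1 bed file (bad magic bytes)", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only variant-major (mode 0x01) bed files are supported",
         call. = FALSE)
  }
  bpv <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bpv * m) {
    stop(sprintf("truncated bed file: expected %d data bytes, found %d",
                 bpv * m, length(body)), call. = FALSE)
  }
  if (m == 0) {
    return(geno_matrix(matrix(integer(0), n, 0,
                              dimnames = list(fam$V2, character(0)))))
  }
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m, dimnames = list(fam$V2, bim$V2))
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  geno_matrix(dosage)
}

#' Write / read a pedigree TSV
#'
#' Columns `IID`, `SIRE`, `DAM`, `SEX`, `FAMILY`, `GENERATION`; unknown
#' parents are written as `UNKNOWN`.
#'
#' @param pedigree A pedigree tibble.
#' @param path Output path.
#' @return Invisibly the path ([write_pedigree_tsv()]) or a pedigree tibble
#'   ([read_pedigree_tsv()]).
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  out <- data.frame(
    IID = pedigree$id,
    SIRE = ifelse(is.na(pedigree$sire), "UNKNOWN", pedigree$sire),
    DAM = ifelse(is.na(pedigree$dam), "UNKNOWN", pedigree$dam),
    SEX = pedigree$sex,
    FAMILY = pedigree$family_id,
    GENERATION = pedigree$generation
  )
  write_tsv_commented(out, path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  raw <- read_tsv_commented(path)
  new_pedigree(tibble::tibble(
    id = raw$IID,
    sire = ifelse(raw$SIRE == "UNKNOWN", NA_character_, raw$SIRE),
    dam = ifelse(raw$DAM == "UNKNOWN", NA_character_, raw$DAM),
    sex = raw$SEX,
    family_id = raw$FAMILY,
    generation = as.integer(raw$GENERATION)
  ))
}

#' Write / read a phenotype TSV
#'
#' Header `IID TRAIT TRUE_G TRUE_F [covariates...]`; simulation-truth
#' columns are included when present.
#'
#' @param pheno A phenotype tibble.
#' @param path Output path.
#' @return Invisibly the path, or the phenotype tibble when reading.
#' @export
write_pheno_tsv <- function(pheno, path) {
  out <- data.frame(IID = pheno$id, TRAIT = pheno$trait)
  if ("true_g" %in% names(pheno)) out$TRUE_G <- pheno$true_g
  if ("true_f" %in% names(pheno)) out$TRUE_F <- pheno$true_f
  extra <- setdiff(names(pheno), c("id", "trait", "true_g", "true_f"))
  for (col in extra) out[[toupper(col)]] <- pheno[[col]]
  write_tsv_commented(out, path)
}

#' @rdname write_pheno_tsv
#' @param trait_type `"quantitative"` or `"binary"`.
#' @export
read_pheno_tsv <- function(path, trait_type = "quantitative") {
  raw <- read_tsv_commented(path)
  out <- tibble::tibble(id = as.character(raw$IID), trait = raw$TRAIT)
  if ("TRUE_G" %in% names(raw)) out$true_g <- raw$TRUE_G
  if ("TRUE_F" %in% names(raw)) out$true_f <- raw$TRUE_F
  extra <- setdiff(names(raw), c("IID", "TRAIT", "TRUE_G", "TRUE_F"))
  for (col in extra) out[[tolower(col)]] <- raw[[col]]
  new_phenotype_tbl(out, trait_type)
}

#' Persist a relationship matrix as TSV
#'
#' Writes the lower triangle (including diagonal) as `(id_i, id_j, value)`
#' at 12 significant digits, plus an id-order sidecar `<path>.ids`; the
#' reader rebuilds the symmetric matrix and round-trips the values exactly
#' at that precision.
#'
#' @param x A [rel_matrix()].
#' @param path Output TSV path.
#' @return Invisibly the path, or a `rel_matrix` when reading.
#' @export
write_relmat_tsv <- function(x, path) {
  stopifnot(inherits(x, "rel_matrix"))
  tri <- tidy(x, diagonal = TRUE)
  tri$value <- sprintf("%.12g", tri$value)
  con <- file(path, "w")
  writeLines(c(file_header(), sprintf("# kind=%s", x$kind)), con)
  utils::write.table(tri, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(x$ids, paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_relmat_tsv
#' @export
read_relmat_tsv <- function(path) {
  header <- readLines(path, n = 5)
  kind_line <- grep("^# kind=", header, value = TRUE)
  kind <- if (length(kind_line)) sub("^# kind=", "", kind_line[1]) else "G"
  tri <- read_tsv_commented(path)
  ids <- readLines(paste0(path, ".ids"))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(tri$id_i, ids)
  j <- match(tri$id_j, ids)
  m[cbind(i, j)] <- as.numeric(tri$value)
  m[cbind(j, i)] <- as.numeric(tri$value)
  rel_matrix(m, kind)
}

#' Persist a study design as TSV
#'
#' Columns `IID`, `ROLE` plus the degree/scale labels in the header
#' comment.
#'
#' @param design A [study_design()].
#' @param path Output path.
#' @return Invisibly the path, or a `study_design` when reading.
#' @export
write_design_tsv <- function(design, path) {
  con <- file(path, "w")
  writeLines(c(
    file_header(seed = attr(design, "seed")),
    sprintf("# degree=%s scale=%s", attr(design, "degree_label"),
            attr(design, "scale_label"))
  ), con)
  utils::write.table(data.frame(IID = design$id, ROLE = design$role), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  header <- readLines(path, n = 5)
  meta <- grep("^# degree=", header, value = TRUE)
  degree <- sub("^# degree=(\\S+) scale=(\\S+)$", "\\1", meta[1])
  scale <- sub("^# degree=(\\S+) scale=(\\S+)$", "\\2", meta[1])
  raw <- read_tsv_commented(path)
  study_design(raw$IID[raw$ROLE == "discovery"],
               raw$IID[raw$ROLE == "target"],
               degree_label = degree, scale_label = scale)
}
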