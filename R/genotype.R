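#' Genotype tables
#'
#' A genotype table is a tibble with one row per individual and the columns
#' `individual_id`, `label` (population or pedigree category) followed by one
#' character column per locus. Each call is the individual's two allele
#' letters in alphabetical order (e.g. `"AG"` for an A/G heterozygote,
#' `"GG"` for a homozygote); `NA` is a missing call. Genotypes are unphased
#' and strand-free: alleles are named nucleotides, not oriented to a
#' reference strand.
#'
#' Locus metadata (scaffold, position, the two segregating alleles) travels
#' in the `"loci"` attribute, a tibble with columns `locus_id`,
#' `scaffold_id`, `scaffold_length`, `position`, `allele_a`, `allele_b`.
#' [loci_info()] retrieves it, reconstructing a minimal version from the
#' observed calls when the attribute has been dropped by data wrangling.
#'
#' @param calls A data frame or matrix of genotype calls (individuals x loci).
#' @param individual_id,label Character vectors, one entry per individual.
#' @param loci Optional locus metadata tibble as described above.
#' @return A genotype tibble.
#' @export
new_genotypes <- function(calls, individual_id, label, loci = NULL) {
  calls <- as.data.frame(calls, optional = TRUE, stringsAsFactors = FALSE)
  if (anyDuplicated(individual_id)) {
    abort(paste0("duplicate individual_id: ",
                 paste(unique(individual_id[duplicated(individual_id)]), collapse = ", ")))
  }
  if (anyDuplicated(names(calls))) {
    abort("duplicate locus ids in call columns")
  }
  geno <- tibble(individual_id = as.character(individual_id),
                 label = as.character(label))
  geno <- dplyr::bind_cols(geno, as_tibble(calls))
  validate_genotypes(geno)
  if (!is.null(loci)) {
    stopifnot(identical(loci$locus_id, locus_ids(geno)))
    attr(geno, "loci") <- as_tibble(loci)
  }
  geno
}

validate_genotypes <- function(geno) {
  stopifnot(is.data.frame(geno))
  if (!all(c("individual_id", "label") %in% names(geno))) {
    abort("genotype table must have individual_id and label columns")
  }
  ids <- locus_ids(geno)
  for (l in ids) {
    x <- geno[[l]]
    bad <- !is.na(x) & !grepl("^[A-Z]{2}$", x)
    if (any(bad)) {
      abort(paste0("invalid genotype call(s) at locus ", l, ": ",
                   paste(unique(x[bad]), collapse = ", ")))
    }
  }
  invisible(geno)
}

#' Locus columns of a genotype table
#' @param geno A genotype tibble.
#' @return Character vector of locus ids (in column order).
#' @export
locus_ids <- function(geno) {
  setdiff(names(geno), c("individual_id", "label"))
}

#' @rdname new_genotypes
#' @param geno A genotype tibble.
#' @export
loci_info <- function(geno) {
  loci <- attr(geno, "loci")
  ids <- locus_ids(geno)
  if (!is.null(loci) && all(ids %in% loci$locus_id)) {
    return(loci[match(ids, loci$locus_id), ])
  }
  # reconstruct: alleles taken alphabetically from observed letters
  alleles <- lapply(ids, function(l) {
    obs <- sort(unique(unlist(strsplit(geno[[l]][!is.na(geno[[l]])], ""))))
    c(obs, "N", "N")[1:2]
  })
  tibble(locus_id = ids,
         scaffold_id = ids,
         scaffold_length = NA_integer_,
         position = 1L,
         allele_a = vapply(alleles, `[`, "", 1),
         allele_b = vapply(alleles, `[`, "", 2))
}

geno_matrix <- function(geno) {
  m <- as.matrix(geno[, locus_ids(geno), drop = FALSE])
  rownames(m) <- geno$individual_id
  m
}

# sorted two-letter call from two allele vectors
make_call <- function(a1, a2) {
  out <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  out[is.na(a1) | is.na(a2)] <- NA_character_
  out
}

# copies of a given allele letter carried in each call (0/1/2, NA if missing)
allele_copies <- function(calls, allele) {
  (substr(calls, 1, 1) == allele) + (substr(calls, 2, 2) == allele)
}

is_het_call <- function(calls) {
  substr(calls, 1, 1) != substr(calls, 2, 2)
}

#' Read a genotype table
#'
#' Reads the fixed genotype CSV dialect (`individual_id,label,<locus>...`
#' header; calls as two allele letters such as `AG`; `NA` for missing;
#' UTF-8, comma separated) or a 4-digit diploid Genepop file.
#'
#' Genepop carries no population labels: populations are labelled
#' `POP1..POPk` in file order, and allele codes `01`/`02` are mapped to the
#' letters in `loci` when supplied (otherwise to `"A"`/`"B"`).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"genepop"`.
#' @param loci Optional locus metadata used to decode Genepop allele codes.
#' @return A genotype tibble (see [new_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("csv", "genepop"), loci = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format,
         csv = read_genotypes_csv(path, loci),
         genepop = read_genotypes_genepop(path, loci))
}

read_genotypes_csv <- function(path, loci = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty genotype file")
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (length(header) < 2 || header[1] != "individual_id" || header[2] != "label") {
    abort("line 1: malformed header, expected 'individual_id,label,<locus ids>'")
  }
  ids <- header[-(1:2)]
  if (anyDuplicated(ids)) {
    abort(paste0("line 1: duplicate locus id ", ids[duplicated(ids)][1]))
  }
  nfield <- length(header)
  rows <- fields[-1]
  len <- lengths(rows)
  if (any(len != nfield)) {
    abort(paste0("line ", which(len != nfield)[1] + 1L,
                 ": expected ", nfield, " fields, found ", len[len != nfield][1]))
  }
  m <- matrix(trimws(unlist(rows)), ncol = nfield, byrow = TRUE)
  iid <- m[, 1]
  if (anyDuplicated(iid)) {
    abort(paste0("line ", which(duplicated(iid))[1] + 1L,
                 ": duplicate individual_id ", iid[duplicated(iid)][1]))
  }
  calls <- m[, -(1:2), drop = FALSE]
  calls[calls == "NA" | calls == ""] <- NA_character_
  # normalise allele order within calls
  calls[] <- make_call(substr(calls, 1, 1), substr(calls, 2, 2))
  colnames(calls) <- ids
  bad <- !is.na(calls) & !grepl("^[ACGT]{2}$", calls)   # CSV dialect: nucleotides
  if (any(bad)) {
    abort(paste0("line ", which(rowSums(bad) > 0)[1] + 1L,
                 ": unknown genotype token ", calls[bad][1]))
  }
  new_genotypes(calls, iid, m[, 2], loci = loci)
}

read_genotypes_genepop <- function(path, loci = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("malformed Genepop file: too short")
  body <- lines[-1]                       # drop title line
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) abort("malformed Genepop file: no POP line")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  ids <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  ids <- ids[nzchar(ids)]
  if (is.null(loci)) {
    alle <- cbind(rep("A", length(ids)), rep("B", length(ids)))
  } else {
    stopifnot(all(ids %in% loci$locus_id))
    loci <- loci[match(ids, loci$locus_id), ]
    alle <- cbind(loci$allele_a, loci$allele_b)
  }
  pop_of_line <- findInterval(seq_along(body), pop_idx)
  ind_lines <- which(pop_of_line > 0 & !(seq_along(body) %in% pop_idx))
  iid <- character(0); lab <- character(0)
  calls <- matrix(NA_character_, nrow = 0, ncol = length(ids))
  for (j in ind_lines) {
    parts <- strsplit(body[j], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) abort(paste0("Genepop line ", j + 1L, ": missing comma"))
    codes <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(codes) != length(ids)) {
      abort(paste0("Genepop line ", j + 1L, ": expected ", length(ids),
                   " loci, found ", length(codes)))
    }
    a1 <- as.integer(substr(codes, 1, 2))
    a2 <- as.integer(substr(codes, 3, 4))
    row <- make_call(decode_gp(a1, alle), decode_gp(a2, alle))
    row[a1 == 0 | a2 == 0] <- NA_character_
    iid <- c(iid, trimws(parts[1]))
    lab <- c(lab, paste0("POP", pop_of_line[j]))
    calls <- rbind(calls, row)
  }
  colnames(calls) <- ids
  new_genotypes(calls, iid, lab, loci = loci)
}

decode_gp <- function(code, alle) {
  out <- rep(NA_character_, length(code))
  out[code == 1] <- alle[code == 1, 1]
  out[code == 2] <- alle[code == 2, 2]
  if (any(code > 2, na.rm = TRUE)) abort("Genepop allele code > 02: loci must be biallelic")
  out
}

#' Write a genotype table
#'
#' The emitted file re-reads to an equal table with [read_genotypes()]
#' (for Genepop: calls and individual ids round-trip; labels become
#' `POP1..POPk`).
#'
#' @param geno A genotype tibble.
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("csv", "genepop")) {
  format <- match.arg(format)
  validate_genotypes(geno)
  lines <- switch(format,
                  csv = format_genotypes_csv(geno),
                  genepop = format_genotypes_genepop(geno))
  con <- file(path, open = "wb")   # byte-stable: LF endings everywhere
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_genotypes_csv <- function(geno) {
  ids <- locus_ids(geno)
  m <- geno_matrix(geno)
  m[is.na(m)] <- "NA"
  c(paste(c("individual_id", "label", ids), collapse = ","),
    paste(geno$individual_id, geno$label,
          apply(m, 1, paste, collapse = ","), sep = ","))
}

format_genotypes_genepop <- function(geno) {
  ids <- locus_ids(geno)
  loci <- loci_info(geno)
  m <- geno_matrix(geno)
  codes <- matrix("0000", nrow(m), ncol(m))
  for (k in seq_along(ids)) {
    c1 <- ifelse(substr(m[, k], 1, 1) == loci$allele_a[k], "01", "02")
    c2 <- ifelse(substr(m[, k], 2, 2) == loci$allele_a[k], "01", "02")
    codes[, k] <- ifelse(is.na(m[, k]), "0000", paste0(c1, c2))
  }
  out <- c("hybridpanel genotype export", ids)
  for (lab in unique(geno$label)) {
    sel <- which(geno$label == lab)
    out <- c(out, "POP",
             paste0(geno$individual_id[sel], " ,  ",
                    apply(codes[sel, , drop = FALSE], 1, paste, collapse = " ")))
  }
  out
}

#' Subset a genotype table to a marker panel
#'
#' @param geno A genotype tibble.
#' @param locus_ids Locus ids to keep; output column order follows this
#'   request. Individuals are unchanged.
#' @return A genotype tibble restricted to the requested loci.
#' @export
subset_panel <- function(geno, locus_ids) {
  missing_ids <- setdiff(locus_ids, names(geno))
  if (length(missing_ids) > 0) {
    abort(paste0("unknown locus id(s): ", paste(missing_ids, collapse = ", ")))
  }
  out <- geno[, c("individual_id", "label", locus_ids), drop = FALSE]
  loci <- attr(geno, "loci")
  if (!is.null(loci)) {
    attr(out, "loci") <- loci[match(locus_ids, loci$locus_id), ]
  }
  out
}
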