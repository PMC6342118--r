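#' Read a GENEPOP file
#'
#' Parses the GENEPOP 4.x text layout: one title line, locus names (one per
#' line or comma-separated on one line), then `POP` blocks of
#' `id ,  genotype genotype ...` rows. Both the 2-digit and 3-digit allele
#' encodings are supported but must not be mixed; `00`/`000` decodes to
#' missing. POP blocks become group labels (`POP1`, `POP2`, ... or the id of
#' the last individual in the block if `pop_names = "last_id"`).
#' Coordinates are not part of the format and are returned as `NA`.
#'
#' @param path path to a GENEPOP text file.
#' @param pop_names `"index"` (default) or `"last_id"`.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, pop_names = c("index", "last_id")) {
  pop_names <- match.arg(pop_names)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw)]
  if (length(raw) < 3L) stop("not a GENEPOP file: fewer than 3 lines")
  body <- raw[-1L]                       # drop title line
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP line found")
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- unlist(strsplit(locus_lines, "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(trimws(loci))])
  L <- length(loci)
  if (L < 1L) stop("no locus names before first POP line")

  ids <- character(); sexv <- character(); grp <- character()
  rows <- list(); pop_i <- 0L; pop_members <- integer()
  digits <- NA_integer_
  for (k in seq(first_pop, length(body))) {
    line <- body[k]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_i <- pop_i + 1L
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("line ", k + 1L, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    fields <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                       "\\s+")[[1]]
    if (length(fields) != L)
      stop("line ", k + 1L, ": ", length(fields),
           " genotype fields but ", L, " loci declared")
    w <- unique(nchar(fields))
    if (length(w) != 1L || !w %in% c(4L, 6L))
      stop("line ", k + 1L,
           ": genotype fields must all be 4 (2-digit) or 6 (3-digit) chars")
    d <- w %/% 2L
    if (is.na(digits)) digits <- d
    else if (digits != d)
      stop("line ", k + 1L, ": mixed ", digits, "-digit and ", d,
           "-digit allele encodings")
    if (any(!grepl("^[0-9]+$", fields)))
      stop("line ", k + 1L, ": non-numeric genotype field")
    a1 <- as.integer(substr(fields, 1L, d))
    a2 <- as.integer(substr(fields, d + 1L, 2L * d))
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    # GENEPOP allows one-sided zero for haploid data; treat as missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    ids <- c(ids, id)
    grp <- c(grp, as.character(pop_i))
    rows[[length(rows) + 1L]] <- rbind(a1, a2)
    pop_members <- c(pop_members, pop_i)
  }
  n <- length(ids)
  if (n < 1L) stop("no individuals found")
  alleles <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) {
    alleles[i, , 1L] <- rows[[i]][1L, ]
    alleles[i, , 2L] <- rows[[i]][2L, ]
  }
  group <- if (pop_names == "index") paste0("POP", pop_members) else {
    last_id <- vapply(split(ids, pop_members), function(v) v[length(v)], "")
    unname(last_id[as.character(pop_members)])
  }
  genotype_table(id = ids, alleles = alleles, group = group, loci = loci)
}

#' Read / write the delimited genotype-table dialect
#'
#' A UTF-8 delimited text table with comment lines starting `#` and columns
#' `id`, `sex`, `x`, `y`, then two columns per locus named `<locus>_1` and
#' `<locus>_2`. Allele codes are positive integers; an empty field or `NA`
#' is missing. An optional `group` column carries group labels.
#' `write_genotype_table()` writes coordinates with 6 decimals so that a
#' write/read cycle round-trips exactly.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return `read_genotype_table()` returns a [genotype_table()];
#'   `write_genotype_table()` returns `path` invisibly.
#' @export
read_genotype_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  need <- c("id", "sex", "x", "y")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicated id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         " (raw sample ids must be unique; run match_duplicates afterwards)")
  acols <- setdiff(names(df), c(need, "group"))
  if (!length(acols)) stop("no allele columns found")
  if (length(acols) %% 2L != 0L ||
      !all(grepl("_[12]$", acols)))
    stop("allele columns must come in pairs named <locus>_1, <locus>_2")
  loci <- unique(sub("_[12]$", "", acols))
  want <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (!all(want %in% acols)) stop("incomplete allele column pair(s)")
  amat <- as.matrix(df[, want, drop = FALSE])
  amat[amat %in% c("", "NA", "0")] <- NA
  bad <- !is.na(amat) & !grepl("^[0-9]+$", amat)
  if (any(bad))
    stop("non-integer allele token(s): ",
         paste(utils::head(unique(amat[bad]), 5L), collapse = ", "))
  storage.mode(amat) <- "integer"
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  genotype_table(id = df$id, alleles = amat,
                 xy = cbind(num(df$x), num(df$y)),
                 sex = ifelse(df$sex == "", "U", df$sex),
                 group = if ("group" %in% names(df)) df$group,
                 loci = loci)
}

#' @rdname read_genotype_table
#' @param x a `genotype_table` to write.
#' @export
write_genotype_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "genotype_table"))
  L <- n_loci(x)
  amat <- matrix(NA_integer_, n_ind(x), 2L * L)
  amat[, seq(1L, 2L * L, 2L)] <- x$alleles[, , 1L]
  amat[, seq(2L, 2L * L, 2L)] <- x$alleles[, , 2L]
  colnames(amat) <- as.vector(rbind(paste0(x$loci, "_1"),
                                    paste0(x$loci, "_2")))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  df <- data.frame(id = x$id, sex = x$sex,
                   x = fmt(x$xy[, 1]), y = fmt(x$xy[, 2]),
                   amat, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$group)) df$group <- x$group
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
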