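# Plain-text I/O: CSV/TSV genotype tables and the GENEPOP dialect.

#' Read a genotype table (CSV/TSV)
#'
#' Expected layout: one row per individual with metadata columns `id`,
#' `stage`, `x`, `y` (and optionally `cwd_id`, `dbh`, `age`) followed by two
#' columns per locus named `<locus>_1` and `<locus>_2`.  Allele codes are
#' integers (SSR fragment sizes); empty cells, `NA`, `0` and `-9` denote a
#' missing allele.  A locus with either allele missing is treated as missing
#' for that individual.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, else comma.
#' @param format_spec optional named list remapping metadata column names,
#'   e.g. `list(id = "sample", x = "easting")`.
#' @param missing_codes values interpreted as missing alleles.
#' @param plot_extent optional `(width, height)` in metres.
#' @return a [genotype_dataset()]
#' @export
read_genotype_table <- function(path, format_spec = list(),
                                missing_codes = c("", "NA", "0", "-9"),
                                plot_extent = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta_map <- utils::modifyList(
    list(id = "id", stage = "stage", x = "x", y = "y",
         cwd_id = "cwd_id", dbh = "dbh", age = "age"), format_spec)
  need <- unlist(meta_map[c("id", "stage", "x", "y")])
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  locus_cols <- setdiff(names(raw), unlist(meta_map))
  base <- sub("_[12]$", "", locus_cols)
  loci <- unique(base[grepl("_[12]$", locus_cols)])
  for (l in loci)
    if (!all(paste0(l, c("_1", "_2")) %in% locus_cols))
      stop("locus ", l, " lacks one of its two allele columns")
  if (length(loci) == 0) stop("no <locus>_1/<locus>_2 allele columns found")

  parse_allele <- function(v, col) {
    v[v %in% missing_codes] <- NA
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("malformed allele code in column ", col, ", data row ", bad[1],
           ": '", v[bad[1]], "'")
    out
  }
  a1 <- sapply(loci, function(l) parse_allele(raw[[paste0(l, "_1")]], paste0(l, "_1")))
  a2 <- sapply(loci, function(l) parse_allele(raw[[paste0(l, "_2")]], paste0(l, "_2")))
  if (nrow(raw) == 1) { a1 <- t(a1); a2 <- t(a2); colnames(a1) <- colnames(a2) <- loci }
  # one-sided missing -> whole locus missing
  na <- is.na(a1) | is.na(a2)
  a1[na] <- NA; a2[na] <- NA

  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    out <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & raw[[col]] != "NA" & is.na(out))
    if (length(bad))
      stop("malformed numeric in column ", col, ", data row ", bad[1])
    out
  }
  chr <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_character_, nrow(raw)))
    v <- raw[[col]]; v[v %in% c("", "NA")] <- NA; v
  }
  info <- data.frame(id = raw[[meta_map$id]], stage = raw[[meta_map$stage]],
                     x = num(meta_map$x), y = num(meta_map$y),
                     cwd_id = chr(meta_map$cwd_id), dbh = num(meta_map$dbh),
                     age = num(meta_map$age), stringsAsFactors = FALSE)
  genotype_dataset(info, a1, a2, plot_extent = plot_extent)
}

#' Write a genotype table (CSV/TSV)
#'
#' Inverse of [read_genotype_table()]; round-trips losslessly.
#'
#' @param ds a `genotype_dataset`
#' @param path output path; extension selects the separator as in reading.
#' @export
write_genotype_table <- function(ds, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  out <- ds$info
  for (l in locus_names(ds)) {
    out[[paste0(l, "_1")]] <- ds$a1[, l]
    out[[paste0(l, "_2")]] <- ds$a2[, l]
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

# ---- GENEPOP ----------------------------------------------------------------

#' Read a GENEPOP file
#'
#' Supports the 4-digit (2 digits per allele) and 6-digit (3 digits per
#' allele) encodings; allele `000` is missing.  GENEPOP carries no
#' coordinates or metadata, so POP blocks are mapped to growth stages via
#' `pop_stages` and per-individual metadata may be merged from a sidecar
#' table keyed by id.
#'
#' @param path GENEPOP file
#' @param pop_stages character vector, one stage label per POP block in file
#'   order; defaults to `pop1`, `pop2`, ... which will fail dataset
#'   validation unless they are real stage labels — supply it.
#' @param coords optional data.frame with columns `id`, `x`, `y` and
#'   optionally `cwd_id`, `dbh`, `age`, merged by id.
#' @return a [genotype_dataset()] (validated only when stages/coords given)
#' @export
read_genepop <- function(path, pop_stages = NULL, coords = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GENEPOP file: too short")
  body <- lines[-1]                                # drop title line
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP line found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  recs <- body[seq(first_pop, length(body))]
  pop_idx <- cumsum(grepl("^\\s*pop\\s*$", recs, ignore.case = TRUE))
  keep <- !grepl("^\\s*pop\\s*$", recs, ignore.case = TRUE)
  recs <- recs[keep]; pop_idx <- pop_idx[keep]
  n_pops <- max(pop_idx)
  if (is.null(pop_stages)) pop_stages <- paste0("pop", seq_len(n_pops))
  if (length(pop_stages) != n_pops)
    stop("pop_stages has length ", length(pop_stages), " but file has ",
         n_pops, " POP blocks")

  ids <- character(length(recs))
  a1 <- matrix(NA_integer_, length(recs), length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  width <- NA_integer_
  for (i in seq_along(recs)) {
    parts <- strsplit(recs[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed GENEPOP record: ", recs[i])
    ids[i] <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gts) != length(loci))
      stop("individual ", ids[i], " has ", length(gts), " genotypes, expected ",
           length(loci))
    w <- unique(nchar(gts))
    if (length(w) != 1 || !w %in% c(4L, 6L))
      stop("inconsistent or unsupported allele-code width for ", ids[i],
           " (got ", paste(w, collapse = "/"), "; need 4 or 6 digits)")
    if (is.na(width)) width <- w
    if (w != width) stop("allele-code width changes mid-file at ", ids[i])
    half <- w / 2
    x1 <- as.integer(substr(gts, 1, half))
    x2 <- as.integer(substr(gts, half + 1, w))
    x1[x1 == 0] <- NA; x2[x2 == 0] <- NA
    na <- is.na(x1) | is.na(x2)
    x1[na] <- NA; x2[na] <- NA
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  info <- data.frame(id = ids, stage = pop_stages[pop_idx],
                     x = 0, y = 0, stringsAsFactors = FALSE)
  validate <- TRUE
  if (!is.null(coords)) {
    m <- match(info$id, coords$id)
    if (anyNA(m)) stop("coords table lacks id(s): ",
                       paste(utils::head(info$id[is.na(m)], 5), collapse = ", "))
    for (col in intersect(c("x", "y", "cwd_id", "dbh", "age"), names(coords)))
      info[[col]] <- coords[[col]][m]
  } else validate <- FALSE
  if (!all(info$stage %in% STAGES)) validate <- FALSE
  genotype_dataset(info, a1, a2, validate = validate)
}

#' Write a GENEPOP file
#'
#' One POP block per growth stage present, in `r paste(STAGES, collapse = " < ")`
#' order.  Chooses the 4-digit encoding when all allele codes are < 100,
#' 6-digit otherwise (codes must then be < 1000).
#'
#' @param ds a `genotype_dataset`
#' @param path output path
#' @param title first (comment) line
#' @return `path`, invisibly; stages written are returned as attribute `pops`.
#' @export
write_genepop <- function(ds, path, title = "spatkin export") {
  mx <- max(c(ds$a1, ds$a2), na.rm = TRUE)
  half <- if (mx < 100) 2L else 3L
  if (mx >= 1000) stop("allele codes >= 1000 cannot be GENEPOP-encoded")
  fmt <- function(v) {
    v[is.na(v)] <- 0L
    formatC(v, width = half, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(locus_names(ds), con)
  pops <- intersect(STAGES, unique(ds$info$stage))
  for (st in pops) {
    writeLines("POP", con)
    idx <- which(ds$info$stage == st)
    for (i in idx) {
      g <- paste0(fmt(ds$a1[i, ]), fmt(ds$a2[i, ]))
      writeLines(paste0(ds$info$id[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(structure(path, pops = pops))
}
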