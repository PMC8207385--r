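# Genotype-table data model and I/O.
#
# A genotype_table stores one row per individual and `ploidy` allele-size
# columns per locus.  Nuclear microsatellites are diploid (ploidy 2);
# chloroplast microsatellites are haploid (ploidy 1) and fully linked, so a
# complete cpSSR row is a multilocus haplotype.

#' Construct a genotype table
#'
#' @param ind character vector of individual ids (unique).
#' @param loc character vector assigning each individual to a sampling
#'   location.
#' @param region character vector assigning each individual to a region
#'   (e.g. one of the three Colombian cordilleras); each location must map to
#'   exactly one region.
#' @param alleles integer matrix with `n_loci * ploidy` columns holding
#'   allele sizes; missing copies use [missing_allele()].
#' @param loci character vector of locus names.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param lat,lon optional per-individual coordinates in decimal degrees
#'   (constant within a location).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ind, loc, region, alleles, loci, ploidy,
                           lat = NULL, lon = NULL) {
  n <- length(ind)
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (length(loc) != n || length(region) != n)
    stop("ind, loc and region must have equal length")
  if (anyDuplicated(ind)) stop("individual ids must be unique")
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != n) stop("alleles must have one row per individual")
  if (ncol(alleles) != length(loci) * ploidy)
    stop("alleles must have ploidy columns per locus")
  # one region per location
  map <- unique(data.frame(loc = loc, region = region,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(map$loc))
    stop("each location must map to exactly one region")
  bad <- !is.na(alleles) & alleles <= 0 & alleles != MISSING_ALLELE
  alleles[is.na(alleles) | bad] <- MISSING_ALLELE
  colnames(alleles) <- paste0(rep(loci, each = ploidy), "_",
                              rep(seq_len(ploidy), length(loci)))
  structure(list(ind = as.character(ind), loc = as.character(loc),
                 region = as.character(region), alleles = alleles,
                 loci = as.character(loci), ploidy = ploidy,
                 lat = if (is.null(lat)) rep(NA_real_, n) else as.numeric(lat),
                 lon = if (is.null(lon)) rep(NA_real_, n) else as.numeric(lon)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci (ploidy %d), %d locations, %d regions\n",
              n_ind(x), n_loci(x), x$ploidy, length(unique(x$loc)),
              length(unique(x$region))))
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param table a `genotype_table`.
#' @return An integer count.
#' @export
n_ind <- function(table) length(table$ind)

#' @rdname n_ind
#' @export
n_loci <- function(table) length(table$loci)

#' Allele-size columns of one locus
#' @param table a `genotype_table`.
#' @param locus locus name or index.
#' @return Integer matrix with `ploidy` columns (sentinel = missing).
#' @export
locus_alleles <- function(table, locus) {
  i <- if (is.character(locus)) match(locus, table$loci) else as.integer(locus)
  if (is.na(i) || i < 1 || i > n_loci(table)) stop("unknown locus: ", locus)
  cols <- (i - 1L) * table$ploidy + seq_len(table$ploidy)
  table$alleles[, cols, drop = FALSE]
}

#' Subset a genotype table by individuals
#' @param table a `genotype_table`.
#' @param keep logical or integer index over individuals.
#' @return A `genotype_table` with the retained rows, order preserved.
#' @export
subset_individuals <- function(table, keep) {
  genotype_table(table$ind[keep], table$loc[keep], table$region[keep],
                 table$alleles[keep, , drop = FALSE], table$loci,
                 table$ploidy, table$lat[keep], table$lon[keep])
}

#' Per-individual count of missing loci
#'
#' A locus counts as missing for an individual when any of its allele copies
#' is the sentinel.
#'
#' @param table a `genotype_table`.
#' @return Integer vector, one count per individual.
#' @export
missing_loci_count <- function(table) {
  miss <- table$alleles == MISSING_ALLELE
  grp <- rep(seq_len(n_loci(table)), each = table$ploidy)
  locus_missing <- vapply(seq_len(n_loci(table)), function(l)
    rowSums(miss[, grp == l, drop = FALSE]) > 0, logical(n_ind(table)))
  if (n_ind(table) == 1L) locus_missing <- matrix(locus_missing, nrow = 1)
  as.integer(rowSums(locus_missing))
}

#' Drop individuals with too much missing data
#'
#' Retains individuals with at most `max_missing_loci` loci missing,
#' preserving input order.  The deposited nuclear dataset uses a threshold of
#' one locus.
#'
#' @param table a `genotype_table`.
#' @param max_missing_loci maximum number of missing loci tolerated (>= 0).
#' @return Filtered `genotype_table`.
#' @export
filter_missing <- function(table, max_missing_loci = 1L) {
  stopifnot(max_missing_loci >= 0)
  subset_individuals(table, missing_loci_count(table) <= max_missing_loci)
}

#' Read a genotype table
#'
#' Two dialects are supported.  `"csv"` is the package's long format with
#' header `ind,loc,region,lat,lon,<locus>_1[,<locus>_2]...`.
#' `"genepop"` is a genepop-like text dialect: a title line, one locus name
#' per line (or comma-separated on one line), `POP` separators, and rows
#' `id , 012015 018018 ...` with 3-digit (or 2-digit) fixed-width allele
#' calls; `0` encodes missing.  Genepop carries no region/coordinate
#' metadata, so regions default to one region per population.
#'
#' @param path file path.
#' @param format `"csv"` or `"genepop"`.
#' @param ploidy expected ploidy (1 or 2); checked against the file.
#' @return A `genotype_table`.
#' @export
read_genotype_table <- function(path, format = c("csv", "genepop"),
                                ploidy = 2L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_genotype_csv(path, ploidy)
  else read_genotype_genepop(path, ploidy)
}

read_genotype_csv <- function(path, ploidy) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ind", "loc", "region", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("schema error: header must contain ", paste(need, collapse = ","))
  acols <- setdiff(names(df), need)
  if (length(acols) %% ploidy != 0)
    stop("schema error: ", length(acols),
         " allele columns inconsistent with ploidy ", ploidy)
  suff <- sub(".*_", "", acols)
  if (!all(suff %in% as.character(seq_len(ploidy))))
    stop("schema error: allele columns must be named <locus>_<copy>")
  loci <- unique(sub("_[0-9]+$", "", acols))
  want <- paste0(rep(loci, each = ploidy), "_", rep(seq_len(ploidy),
                                                    length(loci)))
  if (!setequal(want, acols))
    stop("schema error: allele columns do not form <locus>_1..<locus>_",
         ploidy, " blocks")
  al <- as.matrix(df[, want, drop = FALSE])
  bad <- which(!apply(al, 1, function(r)
    all(is.na(r) | r == "" | !is.na(suppressWarnings(as.numeric(r))))))
  if (length(bad))
    stop("parse error: non-numeric allele on data line ", bad[1] + 1L)
  al <- suppressWarnings(matrix(as.integer(as.numeric(al)), nrow = nrow(al)))
  al[is.na(al) | al <= 0] <- MISSING_ALLELE
  genotype_table(df$ind, df$loc, df$region, al, loci, ploidy,
                 df$lat, df$lon)
}

read_genotype_genepop <- function(path, ploidy) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3) stop("parse error: truncated genepop file")
  body <- lines[-1]  # drop title
  pop_idx <- grep("^pop$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("parse error: no POP separator")
  loci_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  ind <- loc <- region <- character(0)
  rows <- list()
  pop <- 0L
  for (k in seq(pop_idx[1], length(body))) {
    line <- body[k]
    if (grepl("^pop$", line, ignore.case = TRUE)) { pop <- pop + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) != 2)
      stop("parse error: expected 'id , alleles' on line ", k + 1L)
    id <- trimws(parts[1])
    calls <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
    if (length(calls) != length(loci))
      stop("parse error: wrong locus count on line ", k + 1L,
           " (individual ", id, ")")
    width <- nchar(calls[1]) / ploidy
    if (width != floor(width) || !all(nchar(calls) == width * ploidy))
      stop("schema error: allele call width inconsistent with ploidy ",
           ploidy, " on line ", k + 1L)
    a <- unlist(lapply(calls, function(cc)
      as.integer(substring(cc, seq(1, nchar(cc), width),
                           seq(width, nchar(cc), width)))))
    ind <- c(ind, id)
    loc <- c(loc, paste0("pop", pop))
    rows[[length(rows) + 1L]] <- a
  }
  al <- do.call(rbind, rows)
  al[al <= 0] <- MISSING_ALLELE
  genotype_table(make.unique(ind), loc, loc, al, loci, ploidy)
}

#' Write a genotype table in the package CSV dialect
#'
#' Missing copies are written as `0`; [read_genotype_table()] restores the
#' sentinel, so write-then-read round-trips exactly.
#'
#' @param table a `genotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  al <- table$alleles
  al[al == MISSING_ALLELE] <- 0L
  df <- data.frame(ind = table$ind, loc = table$loc, region = table$region,
                   lat = table$lat, lon = table$lon, al,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sampling design of a genotype table
#'
#' @param table a `genotype_table`.
#' @return Data frame with one row per location: `loc`, `region`, `lat`,
#'   `lon` (location means), `n_individuals`.
#' @export
sampling_design <- function(table) {
  sp <- split(seq_len(n_ind(table)), table$loc)
  out <- do.call(rbind, lapply(names(sp), function(l) {
    i <- sp[[l]]
    data.frame(loc = l, region = table$region[i[1]],
               lat = mean(table$lat[i]), lon = mean(table$lon[i]),
               n_individuals = length(i), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Snap raw fragment sizes to a motif lattice
#'
#' Simplified automated binning: for each locus an offset is chosen on a
#' candidate grid so that the lattice `offset + k * motif_length` minimises
#' the total absolute snapping error; every allele is then snapped to its
#' nearest lattice point.  Ties in the offset search are broken towards the
#' smallest offset (deterministic, with a message).
#'
#' @param table a `genotype_table` whose allele entries are raw sizes
#'   (may be stored as rounded integers from fractional calls), or a numeric
#'   matrix of raw sizes.
#' @param motif_length repeat-motif length in base pairs (>= 1).
#' @param offset optional fixed lattice offset; `NULL` selects per locus.
#' @return Object of the same kind with binned allele sizes.
#' @export
bin_alleles <- function(table, motif_length, offset = NULL) {
  stopifnot(motif_length >= 1)
  if (is.matrix(table)) return(bin_matrix(table, motif_length, offset))
  ploidy <- table$ploidy
  al <- table$alleles
  for (l in seq_len(n_loci(table))) {
    cols <- (l - 1L) * ploidy + seq_len(ploidy)
    al[, cols] <- bin_matrix(al[, cols, drop = FALSE], motif_length, offset)
  }
  out <- table
  out$alleles <- al
  storage.mode(out$alleles) <- "integer"
  out
}

bin_matrix <- function(x, motif, offset) {
  obs <- x[x != MISSING_ALLELE & !is.na(x)]
  if (!length(obs)) return(x)
  if (is.null(offset)) {
    cand <- seq(0, motif, by = 0.05)
    cand <- cand[cand < motif]
    err <- vapply(cand, function(o)
      sum(abs(obs - (o + motif * round((obs - o) / motif)))), numeric(1))
    best <- which(err <= min(err) + 1e-12)
    if (length(best) > 1)
      message("bin_alleles: offset tie; keeping smallest offset ",
              cand[best[1]])
    offset <- cand[best[1]]
  }
  snap <- function(v) offset + motif * round((v - offset) / motif)
  keep <- x != MISSING_ALLELE & !is.na(x)
  x[keep] <- round(snap(x[keep]))
  x
}
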