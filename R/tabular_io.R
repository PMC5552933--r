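#' @keywords internal
"_PACKAGE"

# Column schemas for the three standard input tables.
.specimen_cols <- c("specimen_id", "species", "location", "site",
                    "litterbag", "d13c", "d15n")
.resource_cols <- c("resource", "location", "d13c_mean", "d13c_sd",
                    "d15n_mean", "d15n_sd", "n")
.census_cols   <- c("species", "location", "litterbag", "count")

# Sniff the field separator from the header line: tab wins if present,
# otherwise comma. Decimal point only (no locale handling).
.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_delim <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df[required]
}

# Parse a character column as numeric; any unparseable entry aborts with the
# 1-based data row number (header excluded).
.parse_numeric <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("non-numeric value ", sQuote(x[bad[1L]]), " in column ",
         sQuote(column), " at data row ", bad[1L], call. = FALSE)
  }
  out
}

#' Read a specimen isotope table
#'
#' Reads a UTF-8 comma- or tab-separated table (separator sniffed from the
#' header) of specimen-level stable-isotope measurements. Required columns:
#' `specimen_id`, `species`, `location`, `site`, `litterbag`, `d13c`, `d15n`.
#' Isotope values are per-mil (permil) delta values.
#'
#' @param path Path to the delimited file.
#' @return A `data.frame` with one row per specimen.
#' @export
read_specimen_table <- function(path) {
  df <- .read_delim(path, .specimen_cols)
  if (nrow(df) == 0L) {
    warning("specimen table ", path, " has a header but no rows")
    df$d13c <- numeric(0)
    df$d15n <- numeric(0)
    return(df)
  }
  df$d13c <- .parse_numeric(df$d13c, "d13c")
  df$d15n <- .parse_numeric(df$d15n, "d15n")
  if (anyDuplicated(df$specimen_id)) {
    dup <- df$specimen_id[duplicated(df$specimen_id)][1L]
    stop("duplicate specimen_id: ", sQuote(dup), call. = FALSE)
  }
  if (!all(is.finite(df$d13c)) || !all(is.finite(df$d15n))) {
    stop("non-finite isotope value in specimen table", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a resource signature table
#'
#' Required columns: `resource`, `location`, `d13c_mean`, `d13c_sd`,
#' `d15n_mean`, `d15n_sd`, `n`. Standard deviations must be non-negative and
#' `n >= 1`; a duplicated (resource, location) pair is an error.
#'
#' @param path Path to the delimited file.
#' @return A `data.frame` with one row per (resource, location).
#' @export
read_resource_table <- function(path) {
  df <- .read_delim(path, .resource_cols)
  for (col in c("d13c_mean", "d13c_sd", "d15n_mean", "d15n_sd", "n")) {
    df[[col]] <- .parse_numeric(df[[col]], col)
  }
  if (any(df$d13c_sd < 0) || any(df$d15n_sd < 0)) {
    stop("negative standard deviation in resource table", call. = FALSE)
  }
  if (any(df$n < 1)) stop("resource n must be >= 1", call. = FALSE)
  key <- paste(df$resource, df$location, sep = " @ ")
  if (anyDuplicated(key)) {
    stop("duplicate (resource, location) pair: ",
         sQuote(key[duplicated(key)][1L]), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a census table of counts per litterbag
#'
#' Required columns: `species`, `location`, `litterbag`, `count`. Counts must
#' be non-negative integers; one record per (species, litterbag). Missing
#' (species, litterbag) pairs are interpreted as zero counts on query
#' ([census_counts()]); a litterbag entirely absent from the table is treated
#' as nonexistent.
#'
#' @param path Path to the delimited file.
#' @return A `data.frame` with one row per recorded (species, litterbag).
#' @export
read_census_table <- function(path) {
  df <- .read_delim(path, .census_cols)
  df$count <- .parse_numeric(df$count, "count")
  if (any(df$count < 0)) stop("negative count in census table", call. = FALSE)
  if (any(df$count != round(df$count))) {
    bad <- df$count[df$count != round(df$count)][1L]
    stop("non-integral count ", bad, " in census table", call. = FALSE)
  }
  df$count <- as.integer(round(df$count))
  key <- paste(df$species, df$location, df$litterbag, sep = " @ ")
  if (anyDuplicated(key)) {
    stop("duplicate (species, litterbag) census record: ",
         sQuote(key[duplicated(key)][1L]), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Dense per-litterbag counts for one species at one location
#'
#' Expands the sparse census records to one count per litterbag present at
#' the location, filling absent (species, litterbag) pairs with zero.
#'
#' @param census Census `data.frame` from [read_census_table()].
#' @param species Species name.
#' @param location Location name.
#' @return Named integer vector of counts, one element per litterbag.
#' @export
census_counts <- function(census, species, location) {
  at_loc <- census[census$location == location, , drop = FALSE]
  if (nrow(at_loc) == 0L) stop("unknown location: ", location, call. = FALSE)
  if (!species %in% census$species) {
    stop("unknown species: ", species, call. = FALSE)
  }
  bags <- sort(unique(at_loc$litterbag))
  rows <- at_loc[at_loc$species == species, , drop = FALSE]
  counts <- stats::setNames(integer(length(bags)), bags)
  counts[rows$litterbag] <- rows$count
  counts
}

#' Mean density per litterbag with standard error
#'
#' Arithmetic mean and standard error (sample SD / sqrt(L)) of a species'
#' counts over all L litterbags at a location, zero counts included.
#'
#' @inheritParams census_counts
#' @return List with `mean`, `se`, and `n_litterbags`.
#' @export
mean_density <- function(census, species, location) {
  counts <- census_counts(census, species, location)
  L <- length(counts)
  m <- mean(counts)
  se <- if (L > 1L) stats::sd(counts) / sqrt(L) else NA_real_
  list(mean = m, se = se, n_litterbags = L)
}

#' Write a table in the package's exchange dialect
#'
#' Tab-separated, UTF-8, header row, no quoting of numerics. Re-reading with
#' the matching reader yields identical records.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable constants of the pipeline. Trophic enrichment factors
#' default to 0.4 permil (carbon) and 2.3 permil (nitrogen) per trophic
#' step; the Jacobian uses a per-capita growth rate of 1; inverse-Jacobian
#' perturbations scale every element by (1 +/- 0.2); the randomization null
#' uses 10 rearranged matrices.
#'
#' @param tef_c,tef_n Trophic enrichment factors (permil) for d13C and d15N.
#' @param mcmc List with `iterations`, `burnin`, `thin`, `chains` for the
#'   mixing-model sampler.
#' @param seed Integer root seed.
#' @param r_growth Per-capita growth rate used in the Jacobian.
#' @param perturbation_fraction Element-wise perturbation fraction in (0,1).
#' @param n_random_matrices Number of rearranged null matrices.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tef_c = 0.4, tef_n = 2.3,
                       mcmc = list(iterations = 30000L, burnin = 10000L,
                                   thin = 10L, chains = 4L),
                       seed = 1L, r_growth = 1,
                       perturbation_fraction = 0.2,
                       n_random_matrices = 10L) {
  stopifnot(perturbation_fraction > 0, perturbation_fraction < 1,
            mcmc$iterations > mcmc$burnin, mcmc$thin >= 1L,
            mcmc$chains >= 1L, n_random_matrices >= 1L)
  structure(list(tef_c = tef_c, tef_n = tef_n, mcmc = mcmc,
                 seed = as.integer(seed), r_growth = r_growth,
                 perturbation_fraction = perturbation_fraction,
                 n_random_matrices = as.integer(n_random_matrices)),
            class = "run_config")
}
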