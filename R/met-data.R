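#' Read plot-level multi-environment trial records from CSV
#'
#' Reads a comma-delimited, UTF-8 file of plot records. The header must
#' contain `genotype`, `environment`, `replicate`, `block` and every
#' requested trait column. Empty cells and the token `"NA"` are treated as
#' explicit missing values; any other non-numeric trait cell is an error.
#'
#' @param path Path to a CSV file.
#' @param trait_columns Character vector of trait column names to read.
#'
#' @return A tibble with columns `genotype`, `environment` (character),
#'   `replicate` (integer), `block` (character) and one double column per
#'   trait, one row per plot.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "genotype,environment,replicate,block,yield",
#'   "G001,E1,1,B1,4.2",
#'   "G001,E1,2,B2,4.6"
#' ), tf)
#' read_met_csv(tf, "yield")
read_met_csv <- function(path, trait_columns) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(), encoding = "UTF-8")
  required <- c("genotype", "environment", "replicate", "block", trait_columns)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    genotype = raw$genotype,
    environment = raw$environment,
    replicate = as.integer(raw$replicate),
    block = raw$block
  )
  if (nrow(out) > 0 && anyNA(out$replicate)) {
    stop("non-integer replicate value(s)", call. = FALSE)
  }
  for (tr in trait_columns) {
    out[[tr]] <- parse_trait_column(raw[[tr]], tr)
  }
  dup <- duplicated(out[c("genotype", "environment", "replicate")])
  if (any(dup)) {
    bad <- out[dup, c("genotype", "environment", "replicate")]
    stop("duplicate (genotype, environment, replicate) triple(s), e.g. ",
         paste(bad$genotype[1], bad$environment[1], bad$replicate[1]),
         call. = FALSE)
  }
  out
}

# Missing tokens: "" and "NA". Everything else must parse as a finite number.
parse_trait_column <- function(x, name) {
  x <- trimws(x)
  miss <- x == "" | x == "NA"
  val <- suppressWarnings(as.numeric(x))
  bad <- !miss & (is.na(val) | !is.finite(val))
  if (any(bad)) {
    stop("non-numeric value in trait '", name, "' at data row ",
         which(bad)[1], ": '", x[which(bad)[1]], "'", call. = FALSE)
  }
  val[miss] <- NA_real_
  val
}

#' Write plot-level MET records to CSV
#'
#' Inverse of [read_met_csv()]: values round-trip exactly as decimal strings.
#'
#' @param records A data frame of plot records as returned by [read_met_csv()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Genotype-by-environment cell-mean table
#'
#' Collapses plot records to a complete genotype x environment matrix of
#' replicate means for one trait. Every cell must have at least one
#' non-missing observation; nothing is imputed.
#'
#' @param records A data frame of plot records (see [read_met_csv()]).
#' @param trait Name of the trait column to average.
#'
#' @return A `two_way_table`: a list with `values` (genotype x environment
#'   matrix of cell means, dimnames set), `genotypes`, `environments`
#'   (in order of first appearance) and `n_reps` (the design replicate count).
#' @export
#' @examples
#' sim <- simulate_met(sim_config(n_genotypes = 10, n_environments = 3))
#' tab <- cell_means(sim$records, "yield")
#' dim(tab$values)
cell_means <- function(records, trait) {
  stopifnot(is.data.frame(records))
  if (!trait %in% names(records)) {
    stop("trait column '", trait, "' not found", call. = FALSE)
  }
  genotypes <- unique(records$genotype)
  environments <- unique(records$environment)
  g <- factor(records$genotype, levels = genotypes)
  e <- factor(records$environment, levels = environments)
  y <- records[[trait]]
  ok <- !is.na(y)
  counts <- table(g[ok], e[ok])
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)
    cells <- paste0("(", genotypes[empty[, 1]], ", ",
                    environments[empty[, 2]], ")")
    stop("cell(s) with no observation: ", paste(cells, collapse = ", "),
         call. = FALSE)
  }
  sums <- tapply(y[ok], list(g[ok], e[ok]), sum)
  values <- sums / as.numeric(counts)
  dimnames(values) <- list(genotypes, environments)
  structure(
    list(values = values, genotypes = genotypes,
         environments = environments,
         n_reps = max(records$replicate)),
    class = "two_way_table"
  )
}

#' @export
print.two_way_table <- function(x, ...) {
  cat("<two_way_table> ", length(x$genotypes), " genotypes x ",
      length(x$environments), " environments, ", x$n_reps,
      " replicate(s) per cell\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.two_way_table <- function(x, ...) x$values

#' Tidy a cell-mean table into long format
#'
#' @param x A `two_way_table`.
#' @param ... Unused.
#' @return A tibble with columns `genotype`, `environment`, `value`.
#' @method tidy two_way_table
#' @export
tidy.two_way_table <- function(x, ...) {
  tibble::tibble(
    genotype = rep(x$genotypes, times = length(x$environments)),
    environment = rep(x$environments, each = length(x$genotypes)),
    value = as.vector(x$values)
  )
}

#' Write a cell-mean table as TSV
#'
#' Genotypes become a `genotype` label column, environments the remaining
#' column headers.
#'
#' @param table A `two_way_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_two_way_tsv <- function(table, path) {
  df <- data.frame(genotype = table$genotypes, table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Additive marginal effects of a two-way table
#'
#' Decomposes cell means into grand mean, genotype main effects (row mean
#' deviations) and environment main effects (column mean deviations). Both
#' effect vectors sum to zero.
#'
#' @param table A `two_way_table` or a numeric matrix.
#' @return A list with `mu` (grand mean), `G` (named per-genotype effects)
#'   and `E` (named per-environment effects).
#' @export
marginal_effects <- function(table) {
  m <- if (inherits(table, "two_way_table")) table$values else as.matrix(table)
  if (anyNA(m)) stop("table has missing cells", call. = FALSE)
  mu <- mean(m)
  list(mu = mu, G = rowMeans(m) - mu, E = colMeans(m) - mu)
}
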