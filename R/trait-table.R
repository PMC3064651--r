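#' Trait columns recognised by the analysis pipeline
#'
#' Names of the numeric trait columns a [trait_table] carries, in canonical
#' order: body mass (g), combined testes mass (g), total epididymal sperm
#' number (x 10^6), and the four ejaculate quality percentages.
#'
#' @return Character vector of column names.
#' @export
trait_names <- function() {
  c("body_mass", "testes_mass", "total_sperm",
    "pct_normal", "pct_acrosome", "pct_live", "pct_motile")
}

#' Names of the four ejaculate quality traits
#'
#' @return Character vector: percentage of morphologically normal sperm,
#'   acrosome-intact sperm, live sperm and motile sperm.
#' @export
quality_trait_names <- function() {
  c("pct_normal", "pct_acrosome", "pct_live", "pct_motile")
}

# percentage-valued columns, bounded in [0, 100]
pct_columns <- function() quality_trait_names()

#' Default per-trait transformation tags
#'
#' The transformation policy applied before every downstream fit: log10 for
#' the strictly positive, right-skewed size and count traits (body mass,
#' testes mass, total sperm number) and no transformation for the bounded
#' percentage traits. Each tag is one of `"none"`, `"log10"` or
#' `"arcsine_sqrt"`.
#'
#' @return Named character vector, one tag per entry of [trait_names()].
#' @export
default_transforms <- function() {
  c(body_mass = "log10", testes_mass = "log10", total_sperm = "log10",
    pct_normal = "none", pct_acrosome = "none", pct_live = "none",
    pct_motile = "none")
}

normalize_species <- function(x) {
  x <- gsub("_", " ", trimws(x))
  gsub("[ ]+", " ", x)
}

#' Construct a validated species-by-trait table
#'
#' A trait table is a `data.frame` with a `species` column, an `n_males`
#' count, and the numeric trait columns of [trait_names()], carrying a
#' per-trait transformation tag as the `"transforms"` attribute. Validation
#' enforces positive masses and counts, percentages within \[0, 100\], unique
#' species names and at least three species.
#'
#' @param df A data frame with columns `species`, `n_males` and the traits.
#' @param transforms Named character vector of transformation tags
#'   (`"none"`, `"log10"` or `"arcsine_sqrt"`), defaulting to
#'   [default_transforms()]. Unnamed traits default to `"none"`.
#' @return A `trait_table` object (a validated data frame).
#' @export
trait_table <- function(df, transforms = default_transforms()) {
  required <- c("species", "n_males", trait_names())
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$species <- normalize_species(as.character(df$species))
  if (nrow(df) < 3L) {
    stop("trait table must contain at least 3 species (got ", nrow(df), ")",
         call. = FALSE)
  }
  dup <- df$species[duplicated(df$species)]
  if (length(dup) > 0L) {
    stop("duplicate species name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("n_males", trait_names())) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("validation error: column '", col, "' is not numeric", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("validation error: missing value in column '", col, "' (row ",
           which(is.na(v))[1L], ")", call. = FALSE)
    }
  }
  check_bounds <- function(col, ok, msg) {
    bad <- which(!ok(df[[col]]))
    if (length(bad) > 0L) {
      stop("validation error: ", msg, " in column '", col, "', row ", bad[1L],
           " (species ", df$species[bad[1L]], ", value ", df[[col]][bad[1L]],
           ")", call. = FALSE)
    }
  }
  check_bounds("n_males", function(v) v > 0 & v == round(v),
               "male count must be a positive integer")
  for (col in c("body_mass", "testes_mass", "total_sperm")) {
    check_bounds(col, function(v) v > 0, "value must be positive")
  }
  for (col in pct_columns()) {
    check_bounds(col, function(v) v >= 0 & v <= 100,
                 "percentage outside [0, 100]")
  }
  tags <- rep("none", length(trait_names()))
  names(tags) <- trait_names()
  if (length(transforms) > 0L) {
    unknown <- setdiff(names(transforms), trait_names())
    if (length(unknown) > 0L) {
      stop("transformation tag for unknown trait(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad_tag <- setdiff(transforms, c("none", "log10", "arcsine_sqrt"))
    if (length(bad_tag) > 0L) {
      stop("unknown transformation tag(s): ", paste(bad_tag, collapse = ", "),
           call. = FALSE)
    }
    tags[names(transforms)] <- transforms
  }
  rownames(df) <- NULL
  attr(df, "transforms") <- tags
  class(df) <- c("trait_table", "data.frame")
  df
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Species-by-trait table:", nrow(x), "species\n")
  tags <- attr(x, "transforms")
  tagged <- names(tags)[tags != "none"]
  if (length(tagged) > 0L) {
    cat("Transformations:",
        paste(sprintf("%s=%s", tagged, tags[tagged]), collapse = ", "), "\n")
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Transformation tags attached to a trait table
#'
#' @param table A [trait_table].
#' @return Named character vector of per-trait tags.
#' @export
transform_tags <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  attr(table, "transforms")
}

#' Read a species-by-trait table from CSV
#'
#' Reads a comma-separated file (UTF-8, header row, decimal points) and
#' validates it with [trait_table()]. Columns can be renamed on the way in
#' through `schema`, a mapping from canonical column names to the names used
#' in the file.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical names
#'   (e.g. `body_mass`) to the file's column names.
#' @param transforms Per-trait transformation tags, see [trait_table()].
#' @return A validated [trait_table]; row order is preserved.
#' @export
read_trait_table <- function(path, schema = NULL,
                             transforms = default_transforms()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("trait table schema error: cannot parse '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("trait table schema error: '", path, "' has no data rows",
         call. = FALSE)
  }
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) {
        stop("trait table schema error: mapped column '", src,
             "' not found in file", call. = FALSE)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  # reject thousands separators / other non-numeric cells with location info
  for (col in intersect(c("n_males", trait_names()), names(df))) {
    if (is.character(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(parsed)) {
        row <- which(is.na(parsed))[1L]
        stop("validation error: non-numeric value '", df[[col]][row],
             "' in column '", col, "', row ", row, call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  trait_table(df, transforms = transforms)
}

#' Write a trait table to CSV
#'
#' @param table A [trait_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The muroid rodent fixture dataset
#'
#' Species-mean body mass, testes mass, total epididymal sperm number and
#' the four ejaculate quality percentages for 18 muroid rodent species
#' (voles and mice of the families Cricetidae/Arvicolinae and Muridae),
#' installed with the package as a CSV fixture.
#'
#' @param transforms Per-trait transformation tags, defaulting to the
#'   package policy [default_transforms()].
#' @return A [trait_table] with 18 species.
#' @export
muroid_traits <- function(transforms = default_transforms()) {
  path <- system.file("extdata", "muroid_traits.csv", package = "spermcomp",
                      mustWork = TRUE)
  read_trait_table(path, transforms = transforms)
}
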