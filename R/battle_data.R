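#' Historical period boundaries
#'
#' The three-century span of the battle compilation is divided into four
#' periods reflecting major transitions in the conduct of war: Pike and
#' Musket (1620--1701), Linear warfare (1702--1792), the Napoleonic Wars
#' (1793--1860) and the American Civil War era (1861--1905). Model fits are
#' performed per period.
#'
#' @return A data.frame with columns `period`, `label`, `from`, `to`.
#' @export
period_table <- function() {
  data.frame(
    period = 1:4,
    label = c("Pike and Musket", "Linear warfare", "Napoleonic Wars",
              "American Civil War"),
    from = c(1620L, 1702L, 1793L, 1861L),
    to = c(1701L, 1792L, 1860L, 1905L)
  )
}

#' Assign a year to its historical period
#'
#' @param year Integer calendar year (vectorized).
#' @return Integer period identifier 1..4, or `NA` for out-of-range years.
#' @export
#' @examples
#' assign_period(c(1701, 1702, 1905, 1610)) # 1 2 4 NA
assign_period <- function(year) {
  pt <- period_table()
  out <- rep(NA_integer_, length(year))
  for (i in seq_len(nrow(pt))) {
    out[!is.na(year) & year >= pt$from[i] & year <= pt$to[i]] <- pt$period[i]
  }
  out
}

#' Default CSV column mapping for battle records
#'
#' Battle tables are plain CSV with one row per engagement: an identifier,
#' the year, the two initial force sizes and the two casualty totals. The
#' mapping from these roles to header names is configurable so the reader is
#' not tied to one dialect.
#'
#' @param id,year,size_a,size_b,casualties_a,casualties_b Header names.
#' @return Named character vector of column names.
#' @export
battle_columns <- function(id = "id", year = "year",
                           size_a = "size_a", size_b = "size_b",
                           casualties_a = "casualties_a",
                           casualties_b = "casualties_b") {
  c(id = id, year = year, size_a = size_a, size_b = size_b,
    casualties_a = casualties_a, casualties_b = casualties_b)
}

#' Construct a battle dataset from raw side-A/side-B records
#'
#' Validates per-row invariants (positive sizes, casualties in
#' `(0, size]`), canonicalizes side orientation (Red = the side with the
#' lower casualty ratio) and assigns historical periods. Zero-casualty
#' records are rejected because the ABC distance divides by historical
#' casualties.
#'
#' @param df data.frame with columns `id`, `year`, `size_a`, `size_b`,
#'   `casualties_a`, `casualties_b`.
#' @param strict If `TRUE` (default) any invalid row aborts with row-indexed
#'   diagnostics; if `FALSE` invalid rows are dropped with a warning listing
#'   them.
#' @return A `battle_dataset`: a data.frame with columns `id`, `year`,
#'   `size_blue`, `size_red`, `cas_blue`, `cas_red`, `swapped`, `period`,
#'   canonically oriented so that `cas_red/size_red <= cas_blue/size_blue`.
#' @export
battle_dataset <- function(df, strict = TRUE) {
  required <- c("id", "year", "size_a", "size_b", "casualties_a", "casualties_b")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  year <- suppressWarnings(as.integer(num(df$year)))
  sa <- num(df$size_a); sb <- num(df$size_b)
  ca <- num(df$casualties_a); cb <- num(df$casualties_b)

  problems <- character(nrow(df))
  bad_size <- is.na(sa) | is.na(sb) | sa <= 0 | sb <= 0
  problems[bad_size] <- "non-numeric or non-positive size"
  bad_cas <- !bad_size &
    (is.na(ca) | is.na(cb) | ca <= 0 | cb <= 0 | ca > sa | cb > sb)
  problems[bad_cas] <- "casualties must satisfy 0 < casualties <= size"
  bad_year <- !bad_size & !bad_cas & is.na(year)
  problems[bad_year] <- "non-numeric year"

  bad <- problems != ""
  if (any(bad)) {
    msgs <- paste0("row ", which(bad), ": ", problems[bad])
    if (strict) {
      stop("invalid battle records:\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    }
    warning("dropped ", sum(bad), " invalid battle record(s):\n  ",
            paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  keep <- !bad
  out <- data.frame(
    id = as.character(df$id)[keep], year = year[keep],
    size_blue = sa[keep], size_red = sb[keep],
    cas_blue = ca[keep], cas_red = cb[keep],
    swapped = rep(FALSE, sum(keep)), stringsAsFactors = FALSE
  )
  out <- canonicalize_sides(out)
  out$period <- assign_period(out$year)
  if (nrow(out) == 0) warning("dataset contains no battles", call. = FALSE)
  class(out) <- c("battle_dataset", "data.frame")
  out
}

#' Canonicalize side orientation
#'
#' Orients each battle so that Red is the side with the lower casualty ratio
#' (casualties / initial size), the convention under which the odds ratio
#' `P` expresses the lower-casualty side's per-soldier advantage. Ties in
#' casualty ratio are broken deterministically: Blue is the side with the
#' larger initial force. The `swapped` column records whether the sides were
#' exchanged.
#'
#' @param df data.frame with columns `size_blue`, `size_red`, `cas_blue`,
#'   `cas_red` (and optionally `swapped`).
#' @return The same frame, canonically oriented; idempotent.
#' @export
canonicalize_sides <- function(df) {
  ratio_blue <- df$cas_blue / df$size_blue
  ratio_red <- df$cas_red / df$size_red
  tie <- ratio_blue == ratio_red
  swap <- (ratio_blue < ratio_red) | (tie & df$size_red > df$size_blue)
  if (is.null(df$swapped)) df$swapped <- FALSE
  if (any(swap)) {
    tmp_s <- df$size_blue[swap]; tmp_c <- df$cas_blue[swap]
    df$size_blue[swap] <- df$size_red[swap]
    df$cas_blue[swap] <- df$cas_red[swap]
    df$size_red[swap] <- tmp_s
    df$cas_red[swap] <- tmp_c
    df$swapped[swap] <- !df$swapped[swap]
  }
  df
}

#' Read battle records from CSV
#'
#' Reads an RFC-4180-style CSV (UTF-8, header row required), maps columns via
#' a configurable [battle_columns()] dialect, validates and canonicalizes.
#'
#' @param path Path to the CSV file.
#' @param columns Column mapping, see [battle_columns()].
#' @param strict Abort on invalid rows (`TRUE`, default) or drop them with a
#'   warning (`FALSE`).
#' @return A `battle_dataset`.
#' @export
read_battles <- function(path, columns = battle_columns(), strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mapped <- df[unname(columns)]
  names(mapped) <- names(columns)
  battle_dataset(mapped, strict = strict)
}

#' Write battle records to CSV
#'
#' Writes the default column dialect (`id`, `year`, `size_a`, `size_b`,
#' `casualties_a`, `casualties_b`), with side A = Blue and side B = Red in
#' the canonical orientation, so that reading the file back round-trips the
#' dataset unchanged.
#'
#' @param ds A `battle_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_battles <- function(ds, path) {
  out <- data.frame(
    id = ds$id, year = ds$year,
    size_a = ds$size_blue, size_b = ds$size_red,
    casualties_a = ds$cas_blue, casualties_b = ds$cas_red
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a dataset to one historical period
#'
#' @param ds A `battle_dataset`.
#' @param period Period identifier in 1..4.
#' @return The subset, preserving order; out-of-range battles are never
#'   included. An empty subset is returned (not an error) when the period
#'   has no battles.
#' @export
filter_period <- function(ds, period) {
  if (!(length(period) == 1 && period %in% 1:4)) {
    stop("unknown period: ", period, " (expected 1..4)", call. = FALSE)
  }
  out <- ds[!is.na(ds$period) & ds$period == period, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.battle_dataset <- function(x, ...) {
  cat("Battle dataset:", nrow(x), "battles\n")
  if (nrow(x) > 0) {
    cat("  years", min(x$year), "-", max(x$year), "\n")
    counts <- table(factor(x$period, levels = 1:4))
    cat("  per period:", paste(sprintf("P%d=%d", 1:4, as.integer(counts)),
                               collapse = " "),
        sprintf("(out of range: %d)\n", sum(is.na(x$period))))
  }
  invisible(x)
}
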