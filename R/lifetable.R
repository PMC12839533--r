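#' Life tables
#'
#' A `life_table` is a data frame with integer column `age` (contiguous,
#' ascending) and numeric column `q`, the annual probability of dying between
#' exact ages `x` and `x + 1`. The final row is the terminal age and must
#' carry `q = 1`: the table asserts that nobody survives past it.
#'
#' @param age Integer vector of contiguous ages.
#' @param q Annual death probabilities in \[0,1\], with `q == 1` at the
#'   terminal age.
#' @return A validated `life_table` data frame.
#' @export
life_table <- function(age, q) {
  lt <- data.frame(age = as.integer(age), q = as.numeric(q))
  validate_life_table(lt)
}

#' @rdname life_table
#' @param lt Candidate life-table data frame.
#' @export
validate_life_table <- function(lt) {
  stopifnot(is.data.frame(lt))
  if (!all(c("age", "q") %in% names(lt))) {
    stop("life table needs columns 'age' and 'q'")
  }
  if (nrow(lt) < 1L) stop("life table is empty")
  if (any(!is.finite(lt$age)) || any(lt$age != as.integer(lt$age))) {
    stop("life table ages must be integers")
  }
  if (any(diff(lt$age) != 1L)) stop("life table ages must be contiguous")
  if (any(!is.finite(lt$q)) || any(lt$q < 0) || any(lt$q > 1)) {
    stop("life table q values must lie in [0,1]")
  }
  if (lt$q[nrow(lt)] != 1) {
    stop("life table must end with q = 1 at the terminal age (got q = ",
         lt$q[nrow(lt)], " at age ", lt$age[nrow(lt)], ")")
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read a life table from delimited text
#'
#' Expects a two-column tab- or comma-delimited file with a header naming the
#' columns `age` and `q`. Parsing is strict: malformed lines are reported by
#' line number.
#'
#' @param path File path.
#' @return A validated `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("life table file '", path,
                               "' has no data rows")
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- trimws(strsplit(lines[1], sep, fixed = TRUE)[[1]])
  ia <- match("age", header)
  iq <- match("q", header)
  if (is.na(ia) || is.na(iq)) {
    stop("life table '", path, "': header must name columns 'age' and 'q'")
  }
  n <- length(lines) - 1L
  age <- numeric(n)
  q <- numeric(n)
  for (i in seq_len(n)) {
    f <- trimws(strsplit(lines[i + 1L], sep, fixed = TRUE)[[1]])
    if (length(f) < max(ia, iq)) {
      stop("life table '", path, "', line ", i + 1L, ": expected at least ",
           max(ia, iq), " fields, got ", length(f))
    }
    a <- suppressWarnings(as.numeric(f[ia]))
    p <- suppressWarnings(as.numeric(f[iq]))
    if (is.na(a) || is.na(p)) {
      stop("life table '", path, "', line ", i + 1L,
           ": non-numeric value ('", f[ia], "', '", f[iq], "')")
    }
    age[i] <- a
    q[i] <- p
  }
  tryCatch(life_table(age, q), error = function(e) {
    stop("life table '", path, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Write a life table as tab-delimited text
#'
#' Inverse of [read_life_table()]; round-trips exactly.
#'
#' @param lt A `life_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("age\tq", con)
  writeLines(sprintf("%d\t%.17g", lt$age, lt$q), con)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> ages %d-%d (%d rows), q[first] = %.2e, terminal q = 1\n",
              min(x$age), max(x$age), nrow(x), x$q[1]))
  invisible(x)
}
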