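#' Landmark set container
#'
#' Bundles 2D landmark configurations for a set of specimens together with
#' semilandmark curve structure and a missing-point mask. Coordinates are in
#' raw digitizing units until aligned with [gpa_align()].
#'
#' @param coords numeric array, n_specimens x n_landmarks x 2.
#' @param specimen_ids character vector of unique specimen labels.
#' @param curves list of integer vectors; each vector lists the landmark
#'   indices along one curve, in order, including the fixed anchor points at
#'   both ends. Interior points of a curve are semilandmarks and may slide.
#' @param missing logical matrix n_specimens x n_landmarks; `TRUE` marks a
#'   landmark that was not observable on that specimen.
#' @param scale optional numeric vector of per-specimen scale factors already
#'   applied to `coords`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, specimen_ids, curves = list(),
                         missing = NULL, scale = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L)
    stop("coords must be an n x k x 2 array")
  n <- dim(coords)[1]; k <- dim(coords)[2]
  specimen_ids <- as.character(specimen_ids)
  if (length(specimen_ids) != n)
    stop("specimen_ids length (", length(specimen_ids),
         ") does not match number of configurations (", n, ")")
  if (anyDuplicated(specimen_ids))
    stop("duplicated specimen ids: ",
         paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "))
  if (is.null(missing)) missing <- matrix(FALSE, n, k)
  missing <- matrix(as.logical(missing), n, k)
  for (cv in curves) {
    if (any(cv < 1L | cv > k)) stop("curve indices outside 1..", k)
  }
  dimnames(coords) <- list(specimen_ids, NULL, c("x", "y"))
  structure(list(coords = coords, specimen_ids = specimen_ids,
                 curves = curves, missing = missing, scale = scale),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  n <- dim(x$coords)[1]; k <- dim(x$coords)[2]
  ns <- length(semilandmark_indices(x))
  cat("Landmark set: ", n, " specimens, ", k, " landmarks (",
      k - ns, " fixed + ", ns, " semilandmarks)\n", sep = "")
  nm <- sum(x$missing)
  if (nm > 0) {
    who <- x$specimen_ids[rowSums(x$missing) > 0]
    cat("Missing points: ", nm, " (", paste(who, collapse = ", "), ")\n",
        sep = "")
  }
  invisible(x)
}

#' Semilandmark indices of a landmark set
#'
#' All curve points are semilandmarks; fixed landmarks are the indices not
#' belonging to any curve. Which semilandmarks actually slide, and along
#' which neighbours, is described separately by a slider table
#' (see [sliders_from_curves()]).
#' @param x a `landmark_set`.
#' @return integer vector (possibly empty), 1-based.
#' @export
semilandmark_indices <- function(x) {
  if (!length(x$curves)) return(integer(0))
  sort(unique(unlist(x$curves)))
}

#' Build a slider table from curve definitions
#'
#' Returns the geomorph-style three-column matrix (before, slide, after)
#' defining the tangent neighbours of each sliding semilandmark. Curves may
#' be anchored at fixed landmarks via `anchors`; anchored curves slide all
#' their points, unanchored curves keep their first and last point fixed.
#'
#' @param curves list of integer vectors of curve point indices, in order.
#' @param anchors optional list (same length) of integer length-2 vectors
#'   giving the fixed landmark index preceding and following each curve.
#' @return integer matrix with columns `before`, `slide`, `after`.
#' @export
sliders_from_curves <- function(curves, anchors = NULL) {
  rows <- list()
  for (ci in seq_along(curves)) {
    cv <- curves[[ci]]
    seqn <- if (!is.null(anchors)) c(anchors[[ci]][1], cv, anchors[[ci]][2])
            else cv
    if (length(seqn) >= 3L)
      for (j in 2:(length(seqn) - 1L))
        rows[[length(rows) + 1L]] <- seqn[(j - 1L):(j + 1L)]
  }
  out <- do.call(rbind, c(rows, list(matrix(integer(0), 0, 3))))
  colnames(out) <- c("before", "slide", "after")
  out
}

#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect: one record per specimen with `LM=` followed by
#' coordinate pairs, optional `CURVES=`/`POINTS=` blocks appending
#' semilandmark curves, and `ID=`, `IMAGE=`, `SCALE=` keys. When `SCALE=` is
#' present the coordinates of that specimen are multiplied by it. Missing
#' landmarks may be encoded either by a sentinel coordinate pair (default
#' `-1 -1`) or by a literal `MISSING` line.
#'
#' @param path file path.
#' @param missing_sentinel numeric length-2 coordinate pair treated as
#'   missing, or `NULL` to disable sentinel detection.
#' @return a [landmark_set()].
#' @export
read_tps <- function(path, missing_sentinel = c(-1, -1)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty TPS file: ", path)
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))

  specs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    n_fixed <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    i <- 2L
    pts <- matrix(NA_real_, 0, 2)
    miss <- logical(0)
    curves <- list()
    id <- NA_character_; scale <- NA_real_

    read_points <- function(n) {
      out <- matrix(NA_real_, n, 2)
      m <- logical(n)
      for (j in seq_len(n)) {
        if (i > length(block)) stop("truncated record (expected ", n,
                                    " points) in ", path)
        ln <- block[i]; i <<- i + 1L
        if (grepl("^MISSING$", ln, ignore.case = TRUE)) {
          m[j] <- TRUE
          next
        }
        xy <- suppressWarnings(as.numeric(
          strsplit(gsub(",", " ", ln), "[[:space:]]+")[[1]]))
        xy <- xy[!is.na(xy)]
        if (length(xy) != 2L) stop("malformed coordinate line '", ln,
                                   "' in ", path)
        if (!is.null(missing_sentinel) && all(xy == missing_sentinel)) {
          m[j] <- TRUE
        } else out[j, ] <- xy
      }
      list(p = out, m = m)
    }

    fx <- read_points(n_fixed)
    pts <- fx$p; miss <- fx$m
    while (i <= length(block)) {
      ln <- block[i]
      if (grepl("^CURVES\\s*=", ln, ignore.case = TRUE)) {
        ncur <- as.integer(sub("^CURVES\\s*=\\s*", "", ln, ignore.case = TRUE))
        i <- i + 1L
        for (cc in seq_len(ncur)) {
          if (!grepl("^POINTS\\s*=", block[i], ignore.case = TRUE))
            stop("expected POINTS= after CURVES= in ", path)
          np <- as.integer(sub("^POINTS\\s*=\\s*", "", block[i],
                               ignore.case = TRUE))
          i <- i + 1L
          cp <- read_points(np)
          idx <- nrow(pts) + seq_len(np)
          pts <- rbind(pts, cp$p); miss <- c(miss, cp$m)
          curves[[cc]] <- idx
        }
      } else if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE); i <- i + 1L
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", ln,
                                ignore.case = TRUE)); i <- i + 1L
      } else if (grepl("^(IMAGE|COMMENT)\\s*=", ln, ignore.case = TRUE)) {
        if (is.na(id))
          id <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
        i <- i + 1L
      } else {
        stop("unrecognized line '", ln, "' in ", path)
      }
    }
    if (!is.na(scale)) pts <- pts * scale
    specs[[r]] <- list(pts = pts, miss = miss, curves = curves,
                       id = if (is.na(id)) paste0("specimen_", r) else id,
                       scale = scale)
  }

  ks <- vapply(specs, function(s) nrow(s$pts), integer(1))
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across specimens (",
         paste(unique(ks), collapse = ", "), "); first offender: ",
         specs[[which(ks != ks[1])[1]]]$id)
  k <- ks[1]
  n <- length(specs)
  coords <- array(NA_real_, c(n, k, 2))
  miss <- matrix(FALSE, n, k)
  for (r in seq_len(n)) {
    coords[r, , ] <- specs[[r]]$pts
    miss[r, ] <- specs[[r]]$miss
  }
  ids <- normalize_labels(vapply(specs, `[[`, character(1), "id"))
  landmark_set(coords, ids, curves = specs[[1]]$curves, missing = miss,
               scale = vapply(specs, `[[`, numeric(1), "scale"))
}

#' Write a TPS landmark file
#'
#' Emits one record per specimen in a dialect [read_tps()] parses losslessly.
#' Curve points are written in `CURVES=`/`POINTS=` blocks; missing landmarks
#' use the sentinel coordinate pair.
#'
#' @param x a [landmark_set()].
#' @param path output file path.
#' @param missing_sentinel coordinate pair written for missing points.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path, missing_sentinel = c(-1, -1), digits = 12) {
  n <- dim(x$coords)[1]; k <- dim(x$coords)[2]
  curve_idx <- unlist(x$curves)
  fixed_idx <- setdiff(seq_len(k), curve_idx)
  fmt <- function(i, j) {
    if (x$missing[i, j]) paste(missing_sentinel, collapse = " ")
    else paste(signif(x$coords[i, j, ], digits), collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    out <- paste0("LM=", length(fixed_idx))
    for (j in fixed_idx) out <- c(out, fmt(i, j))
    if (length(x$curves)) {
      out <- c(out, paste0("CURVES=", length(x$curves)))
      for (cv in x$curves) {
        out <- c(out, paste0("POINTS=", length(cv)))
        for (j in cv) out <- c(out, fmt(i, j))
      }
    }
    out <- c(out, paste0("ID=", x$specimen_ids[i]))
    writeLines(out, con)
  }
  invisible(path)
}

# write_tps emits fixed landmarks first, then curve blocks; sets whose curve
# points already trail the fixed block (the layout read_tps produces) round-
# trip with identical point order.

#' Read a taxon -> predation-strategy table
#'
#' Two-column delimited file (header optional) mapping taxa to one of exactly
#' two regime labels, e.g. specialist/generalist hunting strategies.
#'
#' @param path file path.
#' @param tree optional `phylo`; taxa absent from the tree trigger a warning
#'   and tree tips absent from the table trigger an error.
#' @return named character vector (names = taxa), class `strategy_table`,
#'   with attribute `levels`.
#' @export
read_strategy_table <- function(path, tree = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "", as.is = TRUE,
                          col.names = c("taxon", "regime"), fill = TRUE)
  if (!nrow(df)) stop("empty strategy table: ", path)
  if (tolower(df$taxon[1]) %in% c("taxon", "species", "tip"))
    df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("strategy table has a header but no rows: ", path)
  strategy_table(stats::setNames(df$regime, df$taxon), tree = tree)
}

#' Construct/validate a strategy table
#' @param x named character vector: taxon -> regime label.
#' @param tree optional `phylo` to validate coverage against.
#' @return validated `strategy_table`.
#' @export
strategy_table <- function(x, tree = NULL) {
  nm <- normalize_labels(names(x))
  x <- stats::setNames(trimws(as.character(x)), nm)
  if (anyDuplicated(nm)) stop("duplicated taxa in strategy table: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  lev <- sort(unique(unname(x)))
  if (length(lev) > 2L)
    stop("strategy table must have exactly two regime levels, found: ",
         paste(lev, collapse = ", "))
  if (!is.null(tree)) {
    extra <- setdiff(nm, tree$tip.label)
    if (length(extra)) warning("strategy table taxa absent from tree: ",
                               paste(extra, collapse = ", "))
    absent <- setdiff(tree$tip.label, nm)
    if (length(absent)) stop("tree tips missing a strategy label: ",
                             paste(absent, collapse = ", "))
  }
  structure(x, levels = lev, class = "strategy_table")
}

#' @export
print.strategy_table <- function(x, ...) {
  lev <- attr(x, "levels")
  cat("Strategy table:", length(x), "taxa;",
      paste(sprintf("%s (%d)", lev, tabulate(factor(unclass(x), lev),
                                             length(lev))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Normalize taxon labels for joining across inputs
#'
#' Trims whitespace and replaces internal spaces with underscores; matching
#' is otherwise exact and case-sensitive.
#' @param x character vector.
#' @return character vector.
#' @export
normalize_labels <- function(x) gsub("[ ]+", "_", trimws(x))

#' Check that landmark, tree and strategy inputs name the same taxa
#'
#' @param landmarks a `landmark_set`.
#' @param tree a `phylo`.
#' @param strategy optional `strategy_table`.
#' @return `TRUE` invisibly; otherwise an error whose message lists the
#'   mismatching labels on each side.
#' @export
check_taxon_match <- function(landmarks, tree, strategy = NULL) {
  a <- sort(landmarks$specimen_ids)
  b <- sort(tree$tip.label)
  msg <- character(0)
  if (!identical(a, b))
    msg <- c(msg, paste0("landmarks-only: {",
                         paste(setdiff(a, b), collapse = ", "),
                         "}; tree-only: {",
                         paste(setdiff(b, a), collapse = ", "), "}"))
  if (!is.null(strategy)) {
    s <- sort(names(strategy))
    if (!identical(s, b))
      msg <- c(msg, paste0("strategy-only: {",
                           paste(setdiff(s, b), collapse = ", "),
                           "}; tree-without-strategy: {",
                           paste(setdiff(b, s), collapse = ", "), "}"))
  }
  if (length(msg)) stop("taxon sets do not match: ",
                        paste(msg, collapse = " | "))
  invisible(TRUE)
}
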