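# Gridded risk mapping: exponential class grids, linearisation to
# concentration grids, ingestible size-class selection from the allometric
# fit, and the plastic/zooplankton ratio risk index.
#
# Grids are plain numeric matrices with NA as the missing-data mask; class
# grids carry n_classes and max_exponent as attributes. Row 0 is the
# northernmost row when the source is georeferenced; otherwise grids are
# abstract.

#' Exponential class grid
#'
#' A raster of integer class indices `0..n_classes` indexing
#' order-of-magnitude bins of an underlying quantity; class `x` linearises
#' to `10^((max_exponent / n_classes) * x)`. The canonical inputs are the
#' global plastic count-concentration maps (8 classes spanning 1 to
#' 1,000,000 pieces km^-2, so `max_exponent = 6`) and the zooplankton
#' count-density map (5 classes spanning 1 to 100 mg C m^-3,
#' `max_exponent = 2`).
#'
#' @param values Numeric matrix of class indices; `NA` marks masked cells.
#' @param n_classes Number of classes (class values run 0..n_classes).
#' @param max_exponent Base-10 exponent of the top class.
#' @param units_note Free-text note on the linearised units.
#' @return A `class_grid`.
#' @export
class_grid <- function(values, n_classes, max_exponent, units_note = "") {
  values <- as.matrix(values)
  if (n_classes < 1) invalid_grid("`n_classes` must be >= 1")
  ok <- is.na(values) |
    (values == round(values) & values >= 0 & values <= n_classes)
  if (!all(ok)) {
    cell <- which(!ok, arr.ind = TRUE)[1, ]
    invalid_grid(sprintf(
      "cell [%d, %d] holds %s; class values must be integers in [0, %d]",
      cell[1], cell[2], format(values[cell[1], cell[2]]), n_classes
    ))
  }
  structure(values,
    n_classes = as.integer(n_classes),
    max_exponent = max_exponent,
    units_note = units_note,
    class = c("class_grid", "matrix", "array")
  )
}

#' Concentration grid
#'
#' A raster of nonnegative linear-scale values with `NA` as the mask.
#'
#' @param values Numeric matrix; `NA` marks masked cells.
#' @param units Units string, e.g. `"pieces km^-2"` or `"mg C m^-3"`.
#' @return A `concentration_grid`.
#' @export
concentration_grid <- function(values, units = "") {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) {
    invalid_grid("concentration values must be nonnegative")
  }
  structure(values,
    units = units,
    class = c("concentration_grid", "matrix", "array")
  )
}

#' Linearise an exponential class grid
#'
#' Maps each unmasked class index `x` to `10^((E / C) * x)` where `E` is the
#' grid's `max_exponent` and `C` its `n_classes` — the `y = 10^(6/8)x`
#' transform for the 8-class plastic grids and `y = 10^(2/5)x` for the
#' 5-class zooplankton grid. Class 0 maps to 1 and class `C` to `10^E`;
#' the mask is preserved. The transform is exactly invertible:
#' `x = (C / E) * log10(y)`.
#'
#' @param grid A [class_grid()].
#' @param units Units to stamp on the result.
#' @return A [concentration_grid()] of the same shape.
#' @examples
#' g <- class_grid(matrix(0:8, 3, 3), n_classes = 8, max_exponent = 6)
#' linearise_classes(g)
#' @export
linearise_classes <- function(grid, units = attr(grid, "units_note")) {
  if (!inherits(grid, "class_grid")) {
    invalid_grid("`grid` must be a class_grid")
  }
  e <- attr(grid, "max_exponent")
  c_ <- attr(grid, "n_classes")
  out <- 10^((e / c_) * unclass(grid))
  concentration_grid(out, units = if (is.null(units)) "" else units)
}

#' Plastic size classes
#'
#' Build a size-class table, or retrieve the four canonical classes of the
#' global plastic distribution model: 0.33--1.00, 1.00--4.76, 4.76--20.00
#' and >20.00 mm. Upper bounds are closed; `Inf` marks an unbounded top
#' class.
#'
#' @param lower_mm,upper_mm Ascending, contiguous class bounds (mm).
#' @return A data.frame with columns `lower_mm`, `upper_mm`.
#' @export
size_classes <- function(lower_mm, upper_mm) {
  if (length(lower_mm) != length(upper_mm) || length(lower_mm) < 1) {
    invalid_parameter("`lower_mm` and `upper_mm` must be equal-length, nonempty")
  }
  if (any(lower_mm < 0) || any(upper_mm <= lower_mm)) {
    invalid_parameter("size classes need 0 <= lower_mm < upper_mm")
  }
  if (is.unsorted(lower_mm, strictly = TRUE)) {
    invalid_parameter("size classes must be sorted ascending")
  }
  data.frame(lower_mm = lower_mm, upper_mm = upper_mm)
}

#' @rdname size_classes
#' @export
default_size_classes <- function() {
  size_classes(
    lower_mm = c(0.33, 1.00, 4.76, 20.00),
    upper_mm = c(1.00, 4.76, 20.00, Inf)
  )
}

#' Select the plastic size class ingestible by a community
#'
#' Predicts the longest ingestible plastic for the community's maximum body
#' length via [predict_plastic()] (point prediction) and returns the first
#' size class whose (closed) upper bound is at least that prediction. The
#' gap between the class's upper bound and the prediction is reported as the
#' buffer — deliberately conservative slack against underestimating risk.
#' For the canonical zooplankton case (max body length 13.5 mm, prediction
#' 0.86 mm) this selects the 0.33--1.00 mm class with a 0.14 mm buffer.
#'
#' @param fit An `allometric_fit`.
#' @param max_body_length_mm Largest body length in the community (mm).
#' @param classes Size-class table (see [size_classes()]); must be
#'   ascending and contiguous.
#' @return An `ingestible_class` list: `index`, `lower_mm`, `upper_mm`,
#'   `predicted_mm`, `buffer_mm`.
#' @examples
#' select_ingestible_class(published_fit(), 13.5)
#' @export
select_ingestible_class <- function(fit, max_body_length_mm,
                                    classes = default_size_classes()) {
  stopifnot_scalar_number(max_body_length_mm, "max_body_length_mm")
  if (max_body_length_mm <= 0) {
    invalid_parameter("`max_body_length_mm` must be positive")
  }
  pred <- predict_plastic(fit, max_body_length_mm)$point_mm
  idx <- which(classes$upper_mm >= pred)
  if (length(idx) == 0) {
    abort_plastisize(
      sprintf(
        "predicted ingestible length %.3f mm exceeds the largest class bound",
        pred
      ),
      "plastisize_no_class"
    )
  }
  i <- idx[1]
  structure(
    list(
      index = i,
      lower_mm = classes$lower_mm[i],
      upper_mm = classes$upper_mm[i],
      predicted_mm = pred,
      buffer_mm = classes$upper_mm[i] - pred
    ),
    class = "ingestible_class"
  )
}

#' @export
print.ingestible_class <- function(x, ...) {
  upper <- if (is.finite(x$upper_mm)) sprintf("%.2f", x$upper_mm) else "Inf"
  cat(sprintf(
    "Ingestible size class %d: %.2f-%s mm (predicted %.2f mm, buffer %s mm)\n",
    x$index, x$lower_mm, upper, x$predicted_mm,
    if (is.finite(x$buffer_mm)) sprintf("%.2f", x$buffer_mm) else "Inf"
  ))
  invisible(x)
}

same_shape <- function(grids) {
  dims <- vapply(grids, function(g) paste(dim(g), collapse = "x"), "")
  length(unique(dims)) == 1L
}

#' Total plastic concentration across size classes
#'
#' Elementwise sum of concentration grids (the all-sizes plastic map). A
#' cell is masked only where it is masked in every input; cells missing from
#' some inputs contribute zero.
#'
#' @param grids List of [concentration_grid()]s of identical shape and units.
#' @return A [concentration_grid()].
#' @export
total_plastic <- function(grids) {
  if (!is.list(grids) || length(grids) < 1) {
    invalid_grid("`grids` must be a nonempty list of concentration grids")
  }
  if (!all(vapply(grids, inherits, TRUE, "concentration_grid"))) {
    invalid_grid("all inputs must be concentration_grids")
  }
  if (!same_shape(grids)) invalid_grid("grids differ in shape")
  units <- unique(vapply(grids, attr, "", "units"))
  if (length(units) != 1L) invalid_grid("grids differ in units")
  filled <- lapply(grids, function(g) {
    v <- unclass(g)
    v[is.na(v)] <- 0
    v
  })
  total <- Reduce(`+`, filled)
  all_masked <- Reduce(`&`, lapply(grids, is.na))
  total[all_masked] <- NA_real_
  concentration_grid(total, units = units)
}

#' Plastic-ingestion risk index
#'
#' Elementwise ratio of ingestible plastic concentration (pieces km^-2) to
#' zooplankton density (mg C m^-3). Cells where either input is masked, or
#' where zooplankton density is zero, are masked (no community to be at
#' risk, and no division by zero).
#'
#' @param plastic Ingestible-plastic [concentration_grid()] (pieces km^-2).
#' @param zooplankton Zooplankton density [concentration_grid()] (mg C m^-3).
#' @return A `risk_grid` (a concentration grid subclass) with combined units.
#' @export
risk_index <- function(plastic, zooplankton) {
  if (!inherits(plastic, "concentration_grid") ||
    !inherits(zooplankton, "concentration_grid")) {
    invalid_grid("inputs must be concentration_grids")
  }
  if (!same_shape(list(plastic, zooplankton))) {
    invalid_grid("plastic and zooplankton grids differ in shape")
  }
  p <- unclass(plastic)
  z <- unclass(zooplankton)
  out <- p / z
  out[is.na(p) | is.na(z) | z == 0] <- NA_real_
  structure(out,
    units = sprintf(
      "(%s) per (%s)", attr(plastic, "units"), attr(zooplankton, "units")
    ),
    class = c("risk_grid", "concentration_grid", "matrix", "array")
  )
}

#' Generate synthetic class grids for the risk pipeline
#'
#' Stands in for the digitised published maps: four plastic class grids
#' (8 classes, exponent 6) and one zooplankton class grid (5 classes,
#' exponent 2), sharing a common ~10% random mask (a crude "land" layer so
#' masked cells coincide across layers, as they would on a real coastline).
#'
#' @param shape Grid dimensions, `c(rows, cols)`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param mask_fraction Fraction of cells masked in every layer.
#' @return A list with elements `plastic` (list of four [class_grid()]s,
#'   ordered as [default_size_classes()]) and `zooplankton` (one
#'   [class_grid()]).
#' @examples
#' grids <- generate_synthetic_grids(c(10, 20), seed = 1)
#' @export
generate_synthetic_grids <- function(shape = c(36, 72), seed = NULL,
                                     mask_fraction = 0.1) {
  if (length(shape) != 2L || any(shape < 1)) {
    invalid_parameter("`shape` must be two positive integers")
  }
  with_seed(seed, {
    nr <- shape[1]
    nc <- shape[2]
    mask <- matrix(stats::runif(nr * nc) < mask_fraction, nr, nc)
    draw <- function(n_classes, max_exponent, note) {
      v <- matrix(sample(0:n_classes, nr * nc, replace = TRUE), nr, nc)
      v[mask] <- NA_real_
      class_grid(v, n_classes, max_exponent, note)
    }
    list(
      plastic = lapply(seq_len(4), function(i) {
        draw(8, 6, "pieces km^-2")
      }),
      zooplankton = draw(5, 2, "mg C m^-3")
    )
  })
}

#' Read and write grids as delimited text
#'
#' One raster row per line, whitespace-separated, `NA` for masked cells.
#' Grid metadata travels in `# key: value` header comments so class grids
#' round-trip with their `n_classes` and `max_exponent`.
#'
#' @param grid A `class_grid` or `concentration_grid`.
#' @param path File path.
#' @return `path` invisibly, or the reconstructed grid object.
#' @export
write_grid <- function(grid, path) {
  header <- character()
  if (inherits(grid, "class_grid")) {
    header <- c(
      "# kind: class_grid",
      sprintf("# n_classes: %d", attr(grid, "n_classes")),
      sprintf("# max_exponent: %s", format(attr(grid, "max_exponent"))),
      sprintf("# units_note: %s", attr(grid, "units_note"))
    )
  } else if (inherits(grid, "concentration_grid")) {
    header <- c(
      "# kind: concentration_grid",
      sprintf("# units: %s", attr(grid, "units"))
    )
  }
  body <- apply(unclass(grid), 1, function(row) {
    paste(format(row, digits = 17, trim = TRUE), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) {
    invalid_parameter(sprintf("grid file not found: %s", path))
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_header]) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  rows <- lapply(strsplit(trimws(lines[!is_header]), "\\s+"), function(tok) {
    tok[tok == "NA"] <- NA_character_
    as.numeric(tok)
  })
  if (length(unique(lengths(rows))) != 1L) {
    invalid_grid("grid rows have unequal lengths")
  }
  values <- do.call(rbind, rows)
  kind <- if (is.null(meta$kind)) "concentration_grid" else meta$kind
  if (kind == "class_grid") {
    class_grid(values,
      n_classes = as.integer(meta$n_classes),
      max_exponent = as.numeric(meta$max_exponent),
      units_note = if (is.null(meta$units_note)) "" else meta$units_note
    )
  } else {
    concentration_grid(values,
      units = if (is.null(meta$units)) "" else meta$units
    )
  }
}

#' Read and write size-class tables as delimited text
#'
#' CSV with columns `lower_mm`, `upper_mm`; an empty `upper_mm` marks an
#' unbounded top class (stored as `Inf` in memory).
#'
#' @param classes Size-class data.frame.
#' @param path File path.
#' @return `path` invisibly, or the size-class data.frame.
#' @export
write_size_classes <- function(classes, path) {
  out <- classes
  out$upper_mm[!is.finite(out$upper_mm)] <- NA_real_
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_size_classes
#' @export
read_size_classes <- function(path) {
  if (!file.exists(path)) {
    invalid_parameter(sprintf("size-class table not found: %s", path))
  }
  tbl <- utils::read.csv(path, na.strings = "")
  tbl$upper_mm[is.na(tbl$upper_mm)] <- Inf
  size_classes(tbl$lower_mm, tbl$upper_mm)
}
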