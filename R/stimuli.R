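#' Shape specifications
#'
#' A `shape_spec` describes one stimulus: a closed ordered list of vertices
#' (canvas units, prototypes normalised to a unit bounding box), an optional
#' smooth contour through those vertices, and metadata (category A/B, role,
#' distortion level, whether the shape is shown during pre-exposure).
#'
#' @param shape_id character identifier.
#' @param category `"A"` or `"B"`.
#' @param role `"prototype"` or `"exemplar"`.
#' @param distortion one of `"none"`, `"low"`, `"medium"`, `"high"`, `"fixed"`.
#' @param vertices two-column numeric matrix of (x, y) vertex coordinates.
#' @param contour optional closed polyline through the vertices (two-column
#'   matrix whose first row equals its last), or `NULL` for contour-free
#'   point stimuli.
#' @param seen_in_preexposure logical.
#' @return an object of class `"shape_spec"`.
#' @export
shape_spec <- function(shape_id, category, role, distortion, vertices,
                       contour = NULL, seen_in_preexposure = FALSE) {
  category <- match.arg(category, c("A", "B"))
  role <- match.arg(role, c("prototype", "exemplar"))
  distortion <- match.arg(distortion, c("none", "low", "medium", "high", "fixed"))
  vertices <- as_vertex_matrix(vertices)
  if (!is.null(contour)) {
    contour <- as_vertex_matrix(contour)
    if (!isTRUE(all.equal(contour[1, ], contour[nrow(contour), ],
                          check.attributes = FALSE)))
      stop("contour must be closed (first point equal to last)")
  }
  structure(list(shape_id = as.character(shape_id), category = category,
                 role = role, distortion = distortion, vertices = vertices,
                 contour = contour,
                 seen_in_preexposure = isTRUE(seen_in_preexposure)),
            class = "shape_spec")
}

as_vertex_matrix <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 2 || !is.numeric(v)) stop("vertices must be an n x 2 numeric matrix")
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec %s: category %s, %s (%s distortion), %d vertices%s>\n",
              x$shape_id, x$category, x$role, x$distortion, nrow(x$vertices),
              if (is.null(x$contour)) ", no contour"
              else sprintf(", contour of %d points", nrow(x$contour))))
  invisible(x)
}

#' Periodic cubic interpolation of a closed vertex list
#'
#' Fits a periodic (closed-curve) cubic interpolating spline through the
#' vertices, parameterised by vertex index, and samples it at
#' `points_per_segment` points per inter-vertex segment.  The curve passes
#' exactly through every vertex and is closed: the first output point equals
#' the last.
#'
#' @param vertices n x 2 numeric matrix of vertices of a simple closed polygon
#'   (the closing edge from the last vertex back to the first is implicit).
#' @param points_per_segment integer >= 1; sampling density per segment.
#' @return a `(n * points_per_segment + 1) x 2` matrix; rows
#'   `1, points_per_segment + 1, ...` coincide with the input vertices.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' interpolate_contour(sq, points_per_segment = 1)
interpolate_contour <- function(vertices, points_per_segment = 10) {
  vertices <- as_vertex_matrix(vertices)
  n <- nrow(vertices)
  if (n < 4) stop("a closed shape needs at least 4 vertices")
  points_per_segment <- as.integer(points_per_segment)
  stopifnot(points_per_segment >= 1)
  tt <- 0:n
  tout <- (0:(n * points_per_segment)) / points_per_segment
  x <- spline(tt, c(vertices[, 1], vertices[1, 1]), method = "periodic", xout = tout)$y
  y <- spline(tt, c(vertices[, 2], vertices[1, 2]), method = "periodic", xout = tout)$y
  cbind(x = x, y = y)
}

# translate/scale so the larger bounding-box dimension spans [0, 1];
# aspect ratio is preserved
normalize_bbox <- function(v) {
  v <- as_vertex_matrix(v)
  v[, 1] <- v[, 1] - min(v[, 1])
  v[, 2] <- v[, 2] - min(v[, 2])
  v / max(max(v[, 1]), max(v[, 2]))
}

#' Built-in category prototypes
#'
#' Returns one of the package's fixed seed prototypes.  In the irregular-shape
#' mode (`experiment = 1`) the two prototypes are deterministic 39-vertex
#' "blobs" built from fixed low-order radial harmonics (distinct coefficient
#' sets for A and B), designed to be hard to name but easy to tell apart.  In
#' the familiar-shape mode (`experiment = 2`) prototype A is a 39-point circle
#' outline and prototype B a 39-point square outline.  All prototypes are
#' normalised to a unit bounding box; distortion SDs are expressed in these
#' units.
#'
#' @param category `"A"` or `"B"`.
#' @param experiment 1 (irregular blobs) or 2 (circle/square).
#' @param n_vertices number of defining vertices (default 39).
#' @param contour logical; attach an interpolated contour?
#' @return a [shape_spec()] with `role = "prototype"`.
#' @export
make_prototype <- function(category = c("A", "B"), experiment = 1,
                           n_vertices = 39, contour = (experiment == 1)) {
  category <- match.arg(category)
  stopifnot(experiment %in% c(1, 2), n_vertices >= 4)
  theta <- 2 * pi * (0:(n_vertices - 1)) / n_vertices
  if (experiment == 1) {
    # fixed harmonic amplitudes/phases; chosen once, versioned with the package
    if (category == "A") {
      r <- 1 + 0.28 * cos(2 * theta + 0.40) + 0.16 * sin(3 * theta + 1.10) +
        0.09 * cos(5 * theta + 2.30)
    } else {
      r <- 1 + 0.24 * sin(2 * theta + 2.00) + 0.20 * cos(4 * theta + 0.70) +
        0.08 * sin(7 * theta + 1.50)
    }
    v <- cbind(r * cos(theta), r * sin(theta))
  } else {
    if (category == "A") {
      v <- cbind(cos(theta), sin(theta))
    } else {
      # equally spaced points along a square perimeter, starting at a corner
      s <- 8 * (0:(n_vertices - 1)) / n_vertices  # perimeter arc length, side 2
      seg <- floor(s / 2)
      f <- s - 2 * seg
      v <- matrix(NA_real_, n_vertices, 2)
      v[seg == 0, ] <- cbind(-1 + f[seg == 0], -1)
      v[seg == 1, ] <- cbind(1, -1 + f[seg == 1])
      v[seg == 2, ] <- cbind(1 - f[seg == 2], 1)
      v[seg == 3, ] <- cbind(-1, 1 - f[seg == 3])
    }
  }
  v <- normalize_bbox(v)
  shape_spec(shape_id = sprintf("proto_%s", category), category = category,
             role = "prototype", distortion = "none", vertices = v,
             contour = if (contour) interpolate_contour(v) else NULL)
}

#' Perturb a prototype into an exemplar
#'
#' Displaces every fifth vertex (indices 1, 6, 11, ... in R's 1-based
#' indexing, i.e. positions 0, 5, 10, ... of the ordered vertex list) by
#' independent Gaussian noise with mean 0 and the given SD in both x and y;
#' all other vertices are left untouched, which keeps the re-interpolated
#' spline smooth.  Deterministic given `seed`.
#'
#' @param proto a [shape_spec()] with `role = "prototype"`.
#' @param sd noise standard deviation in canvas units (>= 0).
#' @param seed integer RNG seed.
#' @param shape_id identifier for the new exemplar.
#' @param distortion distortion tag recorded on the exemplar.
#' @param contour logical; re-interpolate a contour? Defaults to whether the
#'   prototype has one.
#' @return a [shape_spec()] with `role = "exemplar"`.
#' @export
perturb_shape <- function(proto, sd, seed, shape_id = NULL,
                          distortion = "fixed", contour = !is.null(proto$contour)) {
  stopifnot(inherits(proto, "shape_spec"))
  if (proto$role != "prototype") stop("perturb_shape expects a prototype")
  if (!is.numeric(sd) || length(sd) != 1 || sd < 0) stop("sd must be a single number >= 0")
  v <- proto$vertices
  idx <- seq(1, nrow(v), by = 5)
  set.seed(seed)
  v[idx, 1] <- v[idx, 1] + rnorm(length(idx), 0, sd)
  v[idx, 2] <- v[idx, 2] + rnorm(length(idx), 0, sd)
  if (is.null(shape_id))
    shape_id <- sprintf("%s_%s_s%d", proto$category, distortion, as.integer(seed))
  shape_spec(shape_id = shape_id, category = proto$category, role = "exemplar",
             distortion = distortion, vertices = v,
             contour = if (contour) interpolate_contour(v) else NULL)
}

#' Generate the exemplars of one category
#'
#' Produces the requested number of exemplars per distortion level by
#' perturbing the category prototype ([perturb_shape()]) at that level's SD.
#' The default corresponds to the irregular-shape design: 18 exemplars split
#' 6/6/6 across low/medium/high distortions with SDs 0.25/0.55/0.75 (in unit
#' bounding-box units).  For the point-stimulus design use
#' `counts = c(fixed = 10)`, `sds = c(fixed = 0.35)` and `contour = FALSE`.
#'
#' @param proto category prototype ([shape_spec()]).
#' @param counts named integer vector, exemplars per distortion level.
#' @param sds named numeric vector of per-level SDs; names must match `counts`.
#' @param seed integer master seed; each exemplar gets a derived sub-seed.
#' @param contour logical; attach interpolated contours to exemplars.
#' @return list of [shape_spec()] exemplars, tagged with their level.
#' @export
generate_category <- function(proto,
                              counts = c(low = 6, medium = 6, high = 6),
                              sds = c(low = 0.25, medium = 0.55, high = 0.75),
                              seed = 1, contour = !is.null(proto$contour)) {
  stopifnot(inherits(proto, "shape_spec"))
  if (any(counts < 0)) stop("exemplar counts must be >= 0")
  if (!all(names(counts) %in% names(sds)))
    stop("every level in counts needs an sd")
  out <- list()
  k <- 0L
  for (level in names(counts)) {
    for (i in seq_len(counts[[level]])) {
      k <- k + 1L
      out[[length(out) + 1L]] <- perturb_shape(
        proto, sd = sds[[level]], seed = derive_seed(seed, k),
        shape_id = sprintf("%s_%s_%02d", proto$category, level, i),
        distortion = level, contour = contour)
    }
  }
  out
}

#' Assemble the 20-item free-sort stimulus set
#'
#' Builds the canonical free-sort set: per category, 3 previously seen
#' exemplars, 6 previously unseen exemplars, and the (unseen) category
#' prototype — 10 items per category, 20 in all.  Selection within the
#' seen/unseen pools is deterministic (lowest shape ids first) and the output
#' is canonically ordered: all A items before all B items, each block sorted
#' by `shape_id`.
#'
#' @param catA,catB lists of [shape_spec()] for each category, each containing
#'   exactly one prototype plus exemplars.
#' @param seen_ids character vector of shape ids shown during pre-exposure;
#'   every id must belong to `catA` or `catB`.
#' @param n_seen,n_unseen per-category counts of seen/unseen exemplars.
#' @return list of 20 [shape_spec()] objects with `seen_in_preexposure` set.
#' @export
assemble_sort_set <- function(catA, catB, seen_ids, n_seen = 3, n_unseen = 6) {
  all_ids <- c(vapply(catA, `[[`, "", "shape_id"), vapply(catB, `[[`, "", "shape_id"))
  unknown <- setdiff(seen_ids, all_ids)
  if (length(unknown))
    stop("seen_ids not found in the supplied categories: ",
         paste(unknown, collapse = ", "))
  pick <- function(shapes) {
    ids <- vapply(shapes, `[[`, "", "shape_id")
    roles <- vapply(shapes, `[[`, "", "role")
    proto <- shapes[roles == "prototype"]
    if (length(proto) != 1) stop("each category must supply exactly one prototype")
    ex <- shapes[roles == "exemplar"]
    ex_ids <- ids[roles == "exemplar"]
    seen <- ex[ex_ids %in% seen_ids]
    unseen <- ex[!ex_ids %in% seen_ids]
    if (length(seen) < n_seen || length(unseen) < n_unseen)
      stop(sprintf("category %s needs >= %d seen and >= %d unseen exemplars",
                   shapes[[1]]$category, n_seen, n_unseen))
    ord <- function(xs) xs[order(vapply(xs, `[[`, "", "shape_id"))]
    seen <- ord(seen)[seq_len(n_seen)]
    unseen <- ord(unseen)[seq_len(n_unseen)]
    seen <- lapply(seen, function(s) { s$seen_in_preexposure <- TRUE; s })
    ord(c(seen, unseen, proto))
  }
  c(pick(catA), pick(catB))
}

#' Build an xAB match-to-sample trial list
#'
#' Constructs the pre-exposure trial list: per block, every one of the 9 A
#' exemplars is paired with every one of the 9 B exemplars (81 trials per
#' block), so 3 blocks give 243 trials.  On each trial one member of the pair
#' is the sample; the two choice options are the pair itself, so the foil is
#' always from the other category.  Which member serves as sample alternates
#' deterministically, the correct side is counterbalanced within block
#' (left/right counts differ by at most 1), and trial order within block is
#' shuffled by `seed`.
#'
#' @param ids_a,ids_b character vectors of exactly 9 exemplar ids per category.
#' @param n_blocks number of blocks (default 3).
#' @param audio `"label"`, `"noise"` or `"none"` — recorded per trial.
#' @param seed integer seed controlling within-block order.
#' @param prototype_ids ids that must not appear (prototypes are excluded from
#'   pre-exposure); supplying one of these among `ids_a`/`ids_b` is an error.
#' @return data.frame with columns `block`, `trial`, `sample_id`, `left_id`,
#'   `right_id`, `correct_side`, `audio`.
#' @export
build_xab_trials <- function(ids_a, ids_b, n_blocks = 3,
                             audio = c("label", "noise", "none"), seed = 1,
                             prototype_ids = character()) {
  audio <- match.arg(audio)
  ids_a <- as.character(ids_a); ids_b <- as.character(ids_b)
  if (length(ids_a) != 9 || length(ids_b) != 9)
    stop("exactly 9 shape ids per category are required")
  if (length(intersect(c(ids_a, ids_b), prototype_ids)))
    stop("prototypes are not presented during pre-exposure")
  if (anyDuplicated(c(ids_a, ids_b))) stop("duplicated shape ids")
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1)
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  set.seed(seed)
  rows <- vector("list", n_blocks)
  for (blk in seq_len(n_blocks)) {
    ord <- sample.int(nrow(pairs))
    p <- pairs[ord, , drop = FALSE]
    trial <- seq_len(nrow(p))
    sample_is_a <- ((blk + trial) %% 2L) == 0L      # alternate which member is queried
    sample_id <- ifelse(sample_is_a, p$a, p$b)
    correct_side <- ifelse(trial %% 2L == 1L, "left", "right")
    foil <- ifelse(sample_is_a, p$b, p$a)
    rows[[blk]] <- data.frame(
      block = blk, trial = trial, sample_id = sample_id,
      left_id = ifelse(correct_side == "left", sample_id, foil),
      right_id = ifelse(correct_side == "right", sample_id, foil),
      correct_side = correct_side, audio = audio,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read shape specifications as JSON
#'
#' Shapes serialise to a JSON array of objects with fields `shape_id`,
#' `category`, `role`, `distortion`, `vertices` (n x 2 array), `contour`
#' (array or null) and `seen_in_preexposure`.
#'
#' @param shapes list of [shape_spec()] objects.
#' @param path file path.
#' @return `read_shapes` returns a list of [shape_spec()]; `write_shapes`
#'   returns `path` invisibly.
#' @export
write_shapes <- function(shapes, path) {
  recs <- lapply(shapes, function(s) {
    list(shape_id = s$shape_id, category = s$category, role = s$role,
         distortion = s$distortion, vertices = unname(s$vertices),
         contour = if (is.null(s$contour)) NULL else unname(s$contour),
         seen_in_preexposure = s$seen_in_preexposure)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_shapes
#' @export
read_shapes <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                              simplifyDataFrame = FALSE)
  to_mat <- function(m) {
    if (is.null(m)) return(NULL)
    if (is.matrix(m)) m else matrix(unlist(m), ncol = 2, byrow = TRUE)
  }
  lapply(recs, function(r) {
    shape_spec(r$shape_id, r$category, r$role, r$distortion,
               vertices = to_mat(r$vertices), contour = to_mat(r$contour),
               seen_in_preexposure = isTRUE(r$seen_in_preexposure))
  })
}
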