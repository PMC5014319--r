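#' Canonical blockworld shape bitmaps
#'
#' Each shape identity is a fixed 10 x 10 binary bitmap, drawn as a line
#' figure (outline): `"cube"` is the border of the square, `"pyramid"` a
#' triangle outline widening towards a full base row. Outlines keep the
#' identity fields sparse, which keeps the learned weight matrix away from
#' saturation and sharpens familiarity discrimination between categories.
#'
#' @param shape_id `"cube"` or `"pyramid"`.
#' @return A 10 x 10 integer 0/1 matrix (rows = y from the top).
#' @examples
#' sum(shape_bitmap("cube"))
#' @export
shape_bitmap <- function(shape_id) {
  if (!shape_id %in% names(.shape_registry)) {
    stop("unknown shape_id: ", shape_id, call. = FALSE)
  }
  .shape_registry[[shape_id]]
}

make_cube_bitmap <- function() {
  m <- matrix(0L, 10, 10)
  m[1, ] <- 1L; m[10, ] <- 1L; m[, 1] <- 1L; m[, 10] <- 1L
  m
}

make_pyramid_bitmap <- function() {
  m <- matrix(0L, 10, 10)
  for (i in 1:10) {
    w <- i
    start <- (10 - w) %/% 2 + 1
    m[i, c(start, start + w - 1L)] <- 1L
  }
  m[10, ] <- 1L
  m
}

.shape_registry <- list(cube = make_cube_bitmap(), pyramid = make_pyramid_bitmap())

#' Shapes known to the blockworld
#' @return A character vector of shape identifiers.
#' @export
blockworld_shapes <- function() names(.shape_registry)

# nearest-neighbour scaling of a binary bitmap to nr x nc
scale_bitmap <- function(m, nr, nc) {
  ri <- pmin(nrow(m), pmax(1L, ceiling(seq_len(nr) * nrow(m) / nr)))
  ci <- pmin(ncol(m), pmax(1L, ceiling(seq_len(nc) * ncol(m) / nc)))
  m[ri, ci, drop = FALSE]
}

new_pictogram <- function(m) {
  storage.mode(m) <- "integer"
  structure(m, class = c("pictogram", class(m)))
}

#' Render an object table into a binary pictogram
#'
#' Draws each object's shape bitmap, scaled to its bounding box, onto a
#' `canvas[2]` x `canvas[1]` binary canvas (rows are y, top-left origin,
#' 0-based object coordinates). Overlapping objects are OR-ed.
#'
#' @param objects A data frame with columns `shape`, `x0`, `y0`, `width`,
#'   `height` (0-based top-left position, pixel extents).
#' @param canvas `c(width, height)` in pixels, default `c(100, 100)`.
#' @return A `"pictogram"`: an integer 0/1 matrix of size height x width.
#' @export
render_pictogram <- function(objects, canvas = c(100, 100)) {
  m <- matrix(0L, nrow = canvas[2], ncol = canvas[1])
  for (k in seq_len(nrow(objects))) {
    o <- objects[k, ]
    check_object_in_canvas(o, canvas)
    bm <- scale_bitmap(shape_bitmap(o$shape), o$height, o$width)
    rows <- (o$y0 + 1):(o$y0 + o$height)
    cols <- (o$x0 + 1):(o$x0 + o$width)
    m[rows, cols] <- pmax(m[rows, cols], bm)
  }
  new_pictogram(m)
}

check_object_in_canvas <- function(o, canvas) {
  if (o$width < 1 || o$height < 1 ||
      o$x0 < 0 || o$y0 < 0 ||
      o$x0 + o$width > canvas[1] || o$y0 + o$height > canvas[2]) {
    stop("object out of canvas: ", o$shape, " at (", o$x0, ", ", o$y0, ") size ",
         o$width, "x", o$height, " on ", canvas[1], "x", canvas[2], call. = FALSE)
  }
  invisible(o)
}

#' Encode an object as a cognitive entity
#'
#' A cognitive entity concatenates three associative fields:
#' an identity field (the shape bitmap, normalized for size and position to a
#' 10 x 10 = 100-bit pattern), an abscissa field (a binary bar of 1s over
#' `[x0, x0 + width)` on a vector of length `canvas[1]`) and an ordinate
#' field (likewise for `[y0, y0 + height)` over `canvas[2]`). With the
#' default 100 x 100 canvas the concatenation has `p = 300` bits.
#'
#' If a `pictogram` is supplied, the identity field is extracted from the
#' pictogram's pixels over the object's bounding box (normalized to 10 x 10
#' by nearest-neighbour scaling) instead of the canonical shape bitmap, so
#' pixel noise propagates into the identity field while the position bars --
#' which come from the already-solved segmentation -- stay exact.
#'
#' @param shape Shape identifier (see [blockworld_shapes()]).
#' @param x0,y0 0-based top-left pixel position.
#' @param width,height Extents in pixels.
#' @param canvas `c(width, height)` of the pictogram.
#' @param pictogram Optional `"pictogram"` to read the identity bitmap from.
#' @return A list of class `"cognitive_entity"` with fields `identity_field`,
#'   `x_field`, `y_field`, `bits` (the concatenation) and `p`.
#' @examples
#' z <- encode_object("cube", x0 = 20, y0 = 30)
#' z$p
#' which(z$x_field == 1)
#' @export
encode_object <- function(shape, x0, y0, width = 10, height = 10,
                          canvas = c(100, 100), pictogram = NULL) {
  o <- list(shape = shape, x0 = x0, y0 = y0, width = width, height = height)
  check_object_in_canvas(o, canvas)
  if (is.null(pictogram)) {
    idm <- shape_bitmap(shape)
  } else {
    crop <- pictogram[(y0 + 1):(y0 + height), (x0 + 1):(x0 + width), drop = FALSE]
    idm <- scale_bitmap(unclass(crop), 10L, 10L)
  }
  identity_field <- as.integer(t(idm)) # row-major flattening
  x_field <- integer(canvas[1]); x_field[(x0 + 1):(x0 + width)] <- 1L
  y_field <- integer(canvas[2]); y_field[(y0 + 1):(y0 + height)] <- 1L
  bits <- c(identity_field, x_field, y_field)
  structure(
    list(identity_field = identity_field, x_field = x_field, y_field = y_field,
         bits = bits, p = length(bits), shape = shape),
    class = "cognitive_entity"
  )
}

#' Recover an object's bounding box from its position bars
#'
#' Inverts the bar encoding of [encode_object()]: the runs of 1s in the
#' abscissa and ordinate fields determine `x0`, `width`, `y0`, `height`
#' exactly.
#'
#' @param entity A `"cognitive_entity"`.
#' @return A one-row tibble with columns `x0`, `width`, `y0`, `height`.
#' @export
decode_entity_bars <- function(entity) {
  xs <- which(entity$x_field == 1L)
  ys <- which(entity$y_field == 1L)
  tibble::tibble(x0 = xs[1] - 1L, width = length(xs),
                 y0 = ys[1] - 1L, height = length(ys))
}

#' Concatenate cognitive entities into a category vector
#'
#' A category of `M` objects is the order-sensitive concatenation of its
#' entities' bit vectors, giving an `M * p`-bit pattern (900 bits for the
#' default three-entity, `p = 300` configuration).
#'
#' @param entities A non-empty list of `"cognitive_entity"` objects sharing
#'   the same `p`.
#' @return An integer binary vector of length `M * p`.
#' @export
encode_category <- function(entities) {
  if (length(entities) == 0) stop("empty entity list", call. = FALSE)
  ps <- vapply(entities, function(e) e$p, integer(1))
  if (length(unique(ps)) > 1L) {
    stop("entities have mixed dimensions: ", paste(unique(ps), collapse = ", "),
         call. = FALSE)
  }
  unlist(lapply(entities, function(e) e$bits), use.names = FALSE)
}

#' Build a scene from an object table
#'
#' A scene is an addressed, ordered collection of cognitive entities: each
#' object gets a unique 1-based address and a flag bit at rest (0). Entities
#' are encoded with [encode_object()]; pass `pictogram` to extract identity
#' fields from rendered (possibly noisy) pixels.
#'
#' @param objects A data frame with columns `shape`, `x0`, `y0`, `width`,
#'   `height`; an optional `address` column must enumerate `1..N`.
#' @param canvas Canvas dimensions `c(width, height)`.
#' @param pictogram Optional pictogram for identity extraction.
#' @return A list of class `"scene"` with `objects` (tibble incl. `address`
#'   and `flag`), `entities` (list of entities in address order), `canvas`,
#'   `N` and `p`.
#' @export
new_scene <- function(objects, canvas = c(100, 100), pictogram = NULL) {
  objects <- tibble::as_tibble(objects)
  n <- nrow(objects)
  if (n == 0) stop("empty scene", call. = FALSE)
  if (!"address" %in% names(objects)) objects$address <- seq_len(n)
  if (!setequal(objects$address, seq_len(n))) {
    stop("scene addresses must be exactly 1..N and unique", call. = FALSE)
  }
  objects <- dplyr::arrange(objects, .data$address)
  objects$flag <- 0L
  entities <- purrr::pmap(
    objects[, c("shape", "x0", "y0", "width", "height")],
    function(shape, x0, y0, width, height) {
      encode_object(shape, x0, y0, width, height, canvas = canvas,
                    pictogram = pictogram)
    }
  )
  structure(
    list(objects = objects, entities = entities, canvas = canvas,
         N = n, p = entities[[1]]$p),
    class = "scene"
  )
}

#' Build a scene directly from bit patterns
#'
#' A low-level scene constructor for working at arbitrary entity dimension
#' `p`: the entities are the given binary vectors, addressed `1..N` in list
#' order, with no pictogram geometry attached. This is the natural fixture
#' for gate-level circuit work, where the oracle width grows with `(M p)^2`
#' and small `p` keeps circuits tractable.
#'
#' @param patterns A list of equal-length binary vectors.
#' @return A `"scene"` whose entities carry only `bits` and `p`.
#' @export
bit_scene <- function(patterns) {
  if (length(patterns) == 0) stop("empty scene", call. = FALSE)
  patterns <- lapply(patterns, as_bits)
  p <- unique(lengths(patterns))
  if (length(p) > 1L) {
    stop("entities have mixed dimensions: ", paste(p, collapse = ", "), call. = FALSE)
  }
  entities <- lapply(patterns, function(b) {
    structure(list(bits = b, p = length(b)), class = "cognitive_entity")
  })
  structure(
    list(objects = tibble::tibble(address = seq_along(patterns), flag = 0L),
         entities = entities, canvas = NULL, N = length(patterns), p = p),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  canvas <- if (is.null(x$canvas)) "no" else paste(x$canvas, collapse = " x ")
  cat(sprintf("Scene: N = %d entities of p = %d bits (%s canvas)\n",
              x$N, x$p, canvas))
  print(x$objects)
  invisible(x)
}

#' Flip bits with a given probability
#'
#' Salt-and-pepper noise: every bit of a pictogram or binary vector is
#' flipped independently with probability `rate`. Deterministic under `seed`.
#'
#' @param x A `"pictogram"` or binary vector.
#' @param rate Flip probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return An object of the same shape and class as `x`.
#' @export
add_noise <- function(x, rate, seed = NULL) {
  if (!is.numeric(rate) || is.na(rate) || rate < 0 || rate > 1) {
    stop("noise rate must be in [0, 1]", call. = FALSE)
  }
  flips <- local_seed(seed, stats::runif(length(x)) < rate)
  out <- x
  out[flips] <- 1L - out[flips]
  out
}

#' The "tower" category template
#'
#' Three stacked 10 x 10 blocks -- a pyramid on top of two cubes -- given as
#' offsets `(dx, dy)` from the tower's top-left anchor, in slot order
#' top-to-bottom. Slot order is the concatenation order of the category
#' vector.
#'
#' @return A tibble with columns `slot`, `shape`, `dx`, `dy`, `width`,
#'   `height`.
#' @export
tower_template <- function() {
  tibble::tibble(
    slot = 1:3,
    shape = c("pyramid", "cube", "cube"),
    dx = c(0L, 0L, 0L),
    dy = c(0L, 10L, 20L),
    width = 10L,
    height = 10L
  )
}

template_objects <- function(template, x0, y0) {
  tibble::tibble(
    shape = template$shape,
    x0 = x0 + template$dx,
    y0 = y0 + template$dy,
    width = template$width,
    height = template$height
  )
}

#' Learn a category at several positions
#'
#' Encodes the category template at each anchor position (canonical,
#' noise-free identity bitmaps), concatenates each instance into an
#' `M * p`-bit vector and auto-associates all of them into one Willshaw
#' memory. For the default tower configuration (ten positions, `p = 300`,
#' `M = 3`) the resulting weight matrix has dimension `n = 900`.
#'
#' @param template A category template such as [tower_template()].
#' @param positions A data frame with columns `x0`, `y0` (anchor per learned
#'   position).
#' @param canvas Canvas dimensions.
#' @return A list of class `"category_memory"`: `W` (the `"lernmatrix"`),
#'   `stored` (matrix of stored vectors, one row per position), `template`,
#'   `positions`, `p`, `M`, `n`.
#' @export
learn_category_positions <- function(template, positions, canvas = c(100, 100)) {
  stored <- lapply(seq_len(nrow(positions)), function(k) {
    objs <- template_objects(template, positions$x0[k], positions$y0[k])
    ents <- purrr::pmap(objs, function(shape, x0, y0, width, height) {
      encode_object(shape, x0, y0, width, height, canvas = canvas)
    })
    encode_category(ents)
  })
  stored <- do.call(rbind, stored)
  W <- learn_pairs(stored)
  structure(
    list(W = W, stored = stored, template = template,
         positions = tibble::as_tibble(positions),
         p = ncol(stored) / nrow(template), M = nrow(template), n = ncol(stored)),
    class = "category_memory"
  )
}

#' @export
print.category_memory <- function(x, ...) {
  cat(sprintf("Category memory: M = %d slots, p = %d, n = %d, %d stored positions\n",
              x$M, x$p, x$n, nrow(x$positions)))
  invisible(x)
}

#' Generate a synthetic blockworld scene with a planted category
#'
#' Emulates the blockworld study conditions: a 100 x 100 binary pictogram
#' holding `n_objects` blocks, among them one instance of the category (by
#' default the three-block tower) planted at one of the learned anchor
#' positions; the remaining objects are random non-overlapping distractor
#' blocks. Pixel noise at `noise_rate` is applied to the rendered pictogram,
#' and the scene's entities are then encoded from the noisy pixels (identity
#' fields) with exact position bars.
#'
#' The learned anchor positions form a deterministic ladder
#' `(x0, y0) = (8 (k - 1), 7 (k - 1))`, `k = 1..n_positions`, so neighbouring
#' stored instances overlap; the category is planted at the middle rung by
#' default. Entity addresses are a seeded permutation of `1..N`, and the
#' ground truth (planted addresses in slot order, anchor, learned positions)
#' is returned for testing.
#'
#' @param n_objects Total number of scene objects `N` (default 10).
#' @param template Category template (default [tower_template()]).
#' @param n_positions Number of learned anchor positions (default 10).
#' @param planted_index Which ladder rung holds the planted instance
#'   (default: the middle one).
#' @param canvas Canvas dimensions.
#' @param noise_rate Pixel flip probability for the pictogram.
#' @param seed Integer seed; the same seed reproduces the world bit for bit.
#' @param max_tries Placement retries per distractor before giving up.
#' @return A list of class `"blockworld"` with `scene`, `pictogram` (noisy),
#'   `clean_pictogram`, `positions` (tibble of learned anchors),
#'   `planted_index`, `planted_anchor`, `planted_addresses` (slot order),
#'   `category_objects` (ground-truth object table), `template`,
#'   `noise_rate`, `seed`.
#' @export
generate_blockworld <- function(n_objects = 10, template = tower_template(),
                                n_positions = 10, planted_index = NULL,
                                canvas = c(100, 100), noise_rate = 0.05,
                                seed = NULL, max_tries = 200) {
  M <- nrow(template)
  if (n_objects < M) stop("n_objects must be at least the category size", call. = FALSE)
  positions <- tibble::tibble(
    x0 = 8L * (seq_len(n_positions) - 1L),
    y0 = 7L * (seq_len(n_positions) - 1L)
  )
  tw <- max(template$dx + template$width)
  th <- max(template$dy + template$height)
  if (any(positions$x0 + tw > canvas[1]) || any(positions$y0 + th > canvas[2])) {
    stop("learned positions do not fit the canvas", call. = FALSE)
  }
  if (is.null(planted_index)) planted_index <- ceiling(n_positions / 2)
  anchor <- positions[planted_index, ]
  cat_objs <- template_objects(template, anchor$x0, anchor$y0)

  # bounding boxes the distractors must avoid: the planted instance (overlap)
  # and exact coincidence with any learned slot (would plant a second copy)
  slot_boxes <- dplyr::bind_rows(lapply(seq_len(n_positions), function(k) {
    template_objects(template, positions$x0[k], positions$y0[k])
  }))

  local_seed(seed, {
    placed <- cat_objs
    shapes <- blockworld_shapes()
    for (d in seq_len(n_objects - M)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        w <- 10L; h <- 10L
        cand <- tibble::tibble(
          shape = sample(shapes, 1),
          x0 = sample.int(canvas[1] - w + 1L, 1) - 1L,
          y0 = sample.int(canvas[2] - h + 1L, 1) - 1L,
          width = w, height = h
        )
        exact_dup <- any(slot_boxes$x0 == cand$x0 & slot_boxes$y0 == cand$y0)
        if (!exact_dup && !any(boxes_overlap(placed, cand))) {
          placed <- dplyr::bind_rows(placed, cand)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("infeasible placement after ", max_tries, " retries", call. = FALSE)
    }
    addresses <- sample.int(n_objects)
    placed$address <- addresses
    clean <- render_pictogram(placed, canvas)
    noisy <- add_noise(clean, noise_rate)
    scene <- new_scene(placed, canvas, pictogram = noisy)
    structure(
      list(scene = scene, pictogram = noisy, clean_pictogram = clean,
           positions = positions, planted_index = planted_index,
           planted_anchor = c(x0 = anchor$x0, y0 = anchor$y0),
           planted_addresses = addresses[seq_len(M)],
           category_objects = cat_objs, template = template,
           noise_rate = noise_rate, seed = seed),
      class = "blockworld"
    )
  })
}

boxes_overlap <- function(boxes, cand) {
  !(boxes$x0 + boxes$width <= cand$x0 | cand$x0 + cand$width <= boxes$x0 |
      boxes$y0 + boxes$height <= cand$y0 | cand$y0 + cand$height <= boxes$y0)
}

#' @export
print.blockworld <- function(x, ...) {
  cat(sprintf("Blockworld: N = %d objects, category planted at (%d, %d), noise %.2f\n",
              x$scene$N, x$planted_anchor["x0"], x$planted_anchor["y0"], x$noise_rate))
  cat("planted addresses (slot order): ",
      paste(x$planted_addresses, collapse = ", "), "\n", sep = "")
  invisible(x)
}
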