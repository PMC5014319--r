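#' Configuration for the tower demonstration
#'
#' Collects the study conditions of the blockworld demonstration: a
#' 100 x 100 canvas holding `N = 10` objects, the three-block tower category
#' (`M = 3`), ten learned tower positions, pictogram noise at rate 0.05 and
#' cosine familiarity at `t = 0.87`. All parts can be overridden.
#'
#' @param canvas Canvas dimensions `c(width, height)`.
#' @param n_objects Scene size `N`.
#' @param template Category template.
#' @param n_positions Number of learned anchor positions.
#' @param noise_rate Pictogram noise rate in `[0, 1]`.
#' @param fam_mode Familiarity statistic (`"cosine"` or `"net"`).
#' @param t Familiarity threshold.
#' @param search Search mode: `"classical-perm"`, `"classical-permrep"` or
#'   `"quantum"` (the demo runs classical perm and quantum in one report).
#' @param r Assumed number of solutions for the quantum search.
#' @param repeats Measurement repeat budget for the quantum search.
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return A list of class `"run_config"`.
#' @export
tower_config <- function(canvas = c(100, 100), n_objects = 10,
                         template = tower_template(), n_positions = 10,
                         noise_rate = 0.05, fam_mode = "cosine", t = 0.87,
                         search = "classical-perm", r = 1, repeats = 100,
                         seed = 42) {
  config <- structure(
    list(canvas = canvas, n_objects = n_objects, template = template,
         n_positions = n_positions, noise_rate = noise_rate,
         fam_mode = fam_mode, t = t, search = search, r = r,
         repeats = repeats, seed = seed, schema = "scenebind/config/1"),
    class = "run_config"
  )
  validate_config(config)
}

#' Validate a run configuration
#'
#' Checks internal consistency and reports every offending field by name.
#'
#' @param config A `"run_config"`.
#' @return The config, invisibly validated; errors list all failing fields.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  M <- nrow(config$template)
  if (!is.numeric(config$canvas) || length(config$canvas) != 2 ||
      any(config$canvas < 1)) {
    problems <- c(problems, "canvas: must be two positive pixel extents")
  }
  if (config$n_objects < M) {
    problems <- c(problems, sprintf("n_objects: must be >= category size M = %d", M))
  }
  if (!config$fam_mode %in% c("cosine", "net")) {
    problems <- c(problems, "fam_mode: must be 'cosine' or 'net'")
  }
  if (config$fam_mode == "cosine" && (config$t < 0 || config$t > 1)) {
    problems <- c(problems, "t: cosine threshold must lie in [0, 1]")
  }
  if (config$fam_mode == "net" && config$t != "auto" &&
      (!is.numeric(config$t) || config$t < 0)) {
    problems <- c(problems, "t: net threshold must be non-negative or 'auto'")
  }
  if (config$noise_rate < 0 || config$noise_rate > 1) {
    problems <- c(problems, "noise_rate: must lie in [0, 1]")
  }
  if (!config$search %in% c("classical-perm", "classical-permrep", "quantum")) {
    problems <- c(problems,
                  "search: must be 'classical-perm', 'classical-permrep' or 'quantum'")
  }
  if (config$r < 1) problems <- c(problems, "r: must be at least 1")
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(config)
}

# deterministic fan-out of the master seed into per-stage child seeds
child_seed <- function(seed, stage) {
  stages <- c(world = 1L, search = 2L, sampling = 3L)
  as.integer((as.numeric(seed) * 101 + stages[[stage]]) %% .Machine$integer.max)
}

#' Run the tower demonstration end to end
#'
#' Generates the blockworld (noisy pictogram, scene, ground truth), learns
#' the tower at its ladder of anchor positions, screens all `Perm(N, M)`
#' candidate tuples classically, and runs the simulated Grover search over
#' the padded `nu^M` index space. The report collects the encoded
#' dimensions, combination counts, matches, the recovered noise-free
#' category vector, the classical query count, the Grover plan and the
#' sampled measurement -- everything the demonstration prints.
#'
#' @param config A `"run_config"` from [tower_config()].
#' @param verbose Emit progress messages to standard error.
#' @return A list of class `"tower_report"`.
#' @export
tower_demo <- function(config = tower_config(), verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  M <- nrow(config$template)

  say("generating blockworld (seed %d)", child_seed(config$seed, "world"))
  world <- generate_blockworld(
    n_objects = config$n_objects, template = config$template,
    n_positions = config$n_positions, canvas = config$canvas,
    noise_rate = config$noise_rate, seed = child_seed(config$seed, "world")
  )
  say("learning %d positions", config$n_positions)
  mem <- learn_category_positions(config$template, world$positions, config$canvas)

  say("classical screen over Perm(%d, %d) tuples", config$n_objects, M)
  mode <- if (identical(config$search, "classical-permrep")) "perm_rep" else "perm"
  bind <- classical_bind(world$scene, mem$W, M, mode = mode,
                         fam_mode = config$fam_mode, t = config$t)

  say("quantum search over nu^M index space")
  marks <- mark_set(world$scene, mem$W, M, config$fam_mode, config$t)
  search <- run_search(world$scene, mem$W, M, r = config$r,
                       fam_mode = config$fam_mode, t = config$t,
                       seed = child_seed(config$seed, "search"),
                       repeats = config$repeats, marks = marks)

  stored_at_planted <- mem$stored[world$planted_index, ]
  planted <- world$planted_addresses
  recovered_ok <- !is.null(bind$recovered) &&
    all(bind$recovered == stored_at_planted)

  structure(
    list(
      schema = "scenebind/report/1",
      seed = config$seed,
      dims = list(p = world$scene$p, n = mem$n, M = M, N = config$n_objects),
      counts = list(
        L = perm_count(config$n_objects, M),
        P = perm_rep_count(config$n_objects, M),
        nu = nu_pad(config$n_objects),
        P_space = nu_pad(config$n_objects)^M
      ),
      planted = list(addresses = planted,
                     anchor = world$planted_anchor,
                     index = world$planted_index),
      classical = list(
        queries = bind$queries,
        n_matches = nrow(bind$matches),
        matches = bind$matches,
        best_tuple = bind$best_tuple,
        planted_passed = any(apply(
          bind$matches[, seq_len(M), drop = FALSE], 1,
          function(r) all(r == planted))),
        recovered = bind$recovered,
        recovered_exact = recovered_ok
      ),
      quantum = list(
        plan = search$plan,
        n_marked = search$n_marked,
        found = search$found,
        oracle_calls = search$oracle_calls,
        status = search$status,
        planted_found = nrow(search$found) > 0 &&
          any(apply(search$found, 1, function(r) all(r == planted)))
      ),
      cost = cost_report(config$n_objects, M, world$scene$p, config$r),
      config = config,
      world = world,
      memory = mem
    ),
    class = "tower_report"
  )
}

#' @export
print.tower_report <- function(x, ...) {
  cat("Tower demonstration report\n")
  cat(sprintf("  dims: p = %d, n = %d (N = %d, M = %d)\n",
              x$dims$p, x$dims$n, x$dims$N, x$dims$M))
  cat(sprintf("  counts: L = %d, P = %d, P' = %d\n",
              x$counts$L, x$counts$P, x$counts$P_space))
  cat(sprintf("  classical: %d queries, %d matches, planted passed: %s, exact recovery: %s\n",
              x$classical$queries, x$classical$n_matches,
              x$classical$planted_passed, x$classical$recovered_exact))
  cat(sprintf("  quantum: k = %d iterations, %d marked, planted found: %s\n",
              x$quantum$plan$k, x$quantum$n_marked, x$quantum$planted_found))
  invisible(x)
}

#' @rdname tidy.bind_result
#' @export
glance.tower_report <- function(x, ...) {
  tibble::tibble(
    p = x$dims$p, n = x$dims$n, L = x$counts$L, P = x$counts$P,
    P_space = x$counts$P_space, queries = x$classical$queries,
    n_matches = x$classical$n_matches,
    planted_passed = x$classical$planted_passed,
    recovered_exact = x$classical$recovered_exact,
    grover_k = x$quantum$plan$k, n_marked = x$quantum$n_marked,
    planted_found = x$quantum$planted_found
  )
}

#' Serialize a tower report to JSON
#'
#' Writes the report's scalar summary (dimensions, counts, query counts,
#' match tuples, recovery flags, Grover plan) as structured JSON with a
#' schema version; the same config and seed always produce a byte-identical
#' file.
#'
#' @param report A `"tower_report"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    schema = report$schema,
    seed = report$seed,
    dims = report$dims,
    counts = report$counts,
    planted = list(addresses = report$planted$addresses,
                   anchor = as.list(report$planted$anchor)),
    classical = list(
      queries = report$classical$queries,
      n_matches = report$classical$n_matches,
      best_tuple = report$classical$best_tuple,
      planted_passed = report$classical$planted_passed,
      recovered_exact = report$classical$recovered_exact,
      recovered = if (is.null(report$classical$recovered)) NULL else
        bits_to_string(report$classical$recovered)
    ),
    quantum = list(
      plan = report$quantum$plan,
      n_marked = report$quantum$n_marked,
      found = report$quantum$found,
      oracle_calls = report$quantum$oracle_calls,
      status = report$quantum$status,
      planted_found = report$quantum$planted_found
    ),
    cost = unclass(report$cost)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
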