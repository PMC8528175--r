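#' Stimulus configuration for random-dot patterns
#'
#' Holds the geometry of a single dot-cloud stimulus in degrees of visual
#' angle. Defaults follow the standard display at 57 cm viewing distance,
#' where 1 degree corresponds to 10 mm: dots of 0.25 deg diameter that may
#' never come closer (centre to centre) than 0.25 deg, connector lines of
#' 1.0--1.5 deg length and 0.05 deg width joining 40% of the dots pairwise.
#'
#' @param numerosity Number of dots (N >= 1).
#' @param connect_fraction Proportion of dots joined pairwise by connector
#'   lines (`f`, default 0.40). `round(f * N)` is coerced to the nearest even
#'   endpoint count (ties resolved downward) so connectors always join whole
#'   pairs.
#' @param min_separation Minimum centre-to-centre dot distance and minimum
#'   dot-to-connector clearance, degrees (default 0.25).
#' @param connector_length_range Closed interval of admissible connector
#'   lengths, degrees (default `c(1.0, 1.5)`).
#' @param connector_width Connector line width, degrees (default 0.05).
#'   Metadata only; clearance is governed by `min_separation`.
#' @param dot_diameter Dot diameter, degrees (default 0.25). Metadata only.
#' @param field_radius Half-extent of the circular patch in which dot centres
#'   are cast, degrees (default 4).
#' @param max_attempts Rejection-sampling cap per element (default 10000).
#' @param max_restarts Whole-pattern restarts before giving up (default 100).
#' @param seed Optional integer seed; when given, generation is fully
#'   deterministic and leaves the global RNG stream untouched.
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(numerosity,
                            connect_fraction = 0.4,
                            min_separation = 0.25,
                            connector_length_range = c(1.0, 1.5),
                            connector_width = 0.05,
                            dot_diameter = 0.25,
                            field_radius = 4.0,
                            max_attempts = 10000L,
                            max_restarts = 100L,
                            seed = NULL) {
  stopifnot(
    length(numerosity) == 1, numerosity >= 1, numerosity == round(numerosity),
    connect_fraction >= 0, connect_fraction <= 1,
    min_separation > 0,
    length(connector_length_range) == 2,
    connector_length_range[1] < connector_length_range[2],
    connector_length_range[1] > 0,
    connector_width > 0, dot_diameter > 0, field_radius > 0,
    max_attempts >= 1, max_restarts >= 1
  )
  structure(
    list(
      numerosity = as.integer(numerosity),
      connect_fraction = connect_fraction,
      min_separation = min_separation,
      connector_length_range = connector_length_range,
      connector_width = connector_width,
      dot_diameter = dot_diameter,
      field_radius = field_radius,
      max_attempts = as.integer(max_attempts),
      max_restarts = as.integer(max_restarts),
      seed = seed
    ),
    class = "stimulus_config"
  )
}

#' Number of connector-endpoint dots implied by a connect fraction
#'
#' `round(f * N)` rounded to the nearest even integer so that endpoints come
#' in whole pairs; exact ties between the two neighbouring even integers are
#' resolved downward. The result is capped at `N` (less one when `N` is odd).
#'
#' @param numerosity Total dot count.
#' @param connect_fraction Proportion of dots to connect.
#' @return Even integer count of connector endpoints.
#' @examples
#' n_connector_endpoints(15, 0.4) # 6
#' n_connector_endpoints(25, 0.4) # 10
#' @export
n_connector_endpoints <- function(numerosity, connect_fraction) {
  k <- connect_fraction * numerosity
  lo <- 2 * floor(k / 2)
  hi <- lo + 2
  n <- if ((k - lo) < (hi - k)) lo else if ((k - lo) > (hi - k)) hi else lo
  cap <- if (numerosity %% 2 == 0) numerosity else numerosity - 1
  as.integer(max(0, min(n, cap)))
}

# Draw a uniform point in the disc of given radius.
runif_disc <- function(radius) {
  r <- radius * sqrt(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  c(r * cos(th), r * sin(th))
}

# Half-white / half-black polarity assignment; odd N gets one extra of a
# randomly chosen polarity.
sample_polarity <- function(n) {
  n_white <- floor(n / 2) + (n %% 2 == 1) * stats::rbinom(1, 1, 0.5)
  sample(c(rep("white", n_white), rep("black", n - n_white)))
}

infeasible_error <- function(constraint, stage) {
  stop(sprintf(
    "infeasible configuration: could not satisfy constraint '%s' during %s",
    constraint, stage
  ), call. = FALSE)
}

#' Generate a pattern of isolated dots
#'
#' Dot centres are cast uniformly in a disc by rejection sampling under the
#' sole constraint that no two centres come closer than
#' `config$min_separation`. Polarity is assigned half white, half black.
#'
#' @param config A [stimulus_config()].
#' @return A `dot_pattern` object with fields `dots` (data frame `x`, `y`,
#'   `polarity`), `connectors` (empty data frame), `config`, and
#'   `kind = "isolated"`.
#' @seealso [generate_connected()], [validate_pattern()]
#' @export
generate_isolated <- function(config) {
  stopifnot(inherits(config, "stimulus_config"))
  gen <- function() generate_pattern_impl(config, n_pairs = 0L)
  if (!is.null(config$seed)) withr::with_seed(config$seed, gen()) else gen()
}

#' Generate a pattern with pairwise-connected dots
#'
#' Two-stage construction. Stage 1 casts connected pairs: the first dot of a
#' pair is cast uniformly, the second at a uniform random length within
#' `connector_length_range` and uniform direction; the pair is accepted only
#' if both dots respect the minimum separation from all previous dots, the
#' connector crosses or touches no previous connector, and the usual
#' dot-to-connector clearance holds in both directions. Stage 2 casts the
#' remaining dots under the constraint of overlapping neither the other dots
#' nor the connector lines. Each dot joins at most one connector.
#'
#' @inheritParams generate_isolated
#' @return A `dot_pattern` object with `kind = "connected"` and one row per
#'   connector in `connectors` (dot indices `i`, `j`).
#' @export
generate_connected <- function(config) {
  stopifnot(inherits(config, "stimulus_config"))
  n_pairs <- n_connector_endpoints(config$numerosity, config$connect_fraction) %/% 2L
  gen <- function() generate_pattern_impl(config, n_pairs = n_pairs)
  if (!is.null(config$seed)) withr::with_seed(config$seed, gen()) else gen()
}

# Core rejection sampler shared by both generators. n_pairs = 0 gives the
# isolated contract.
generate_pattern_impl <- function(config, n_pairs) {
  n <- config$numerosity
  sep <- config$min_separation
  lr <- config$connector_length_range
  R <- config$field_radius

  for (restart in seq_len(config$max_restarts)) {
    dots <- matrix(NA_real_, nrow = n, ncol = 2)
    segs <- vector("list", n_pairs)   # each: list(a=, b=, i=, j=)
    n_placed <- 0L
    ok <- TRUE

    # stage 1: connected pairs
    for (p in seq_len(n_pairs)) {
      placed <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        a <- runif_disc(R)
        len <- stats::runif(1, lr[1], lr[2])
        th <- stats::runif(1, 0, 2 * pi)
        b <- a + len * c(cos(th), sin(th))
        if (sum(b^2) > R^2) next
        if (n_placed > 0) {
          prev <- dots[seq_len(n_placed), , drop = FALSE]
          dd <- pmin(
            sqrt((prev[, 1] - a[1])^2 + (prev[, 2] - a[2])^2),
            sqrt((prev[, 1] - b[1])^2 + (prev[, 2] - b[2])^2)
          )
          if (any(dd < sep)) next
          # new connector must keep clearance from earlier stage-1 dots
          if (any(points_segment_distance(prev, a, b) < sep)) next
        }
        if (p > 1) {
          # no crossing or touching of earlier connectors; earlier
          # connectors must also keep clearance from the new dots
          bad <- FALSE
          for (q in seq_len(p - 1)) {
            s <- segs[[q]]
            if (segments_intersect(a, b, s$a, s$b) ||
                point_segment_distance(a, s$a, s$b) < sep ||
                point_segment_distance(b, s$a, s$b) < sep) {
              bad <- TRUE
              break
            }
          }
          if (bad) next
        }
        dots[n_placed + 1L, ] <- a
        dots[n_placed + 2L, ] <- b
        segs[[p]] <- list(a = a, b = b, i = n_placed + 1L, j = n_placed + 2L)
        n_placed <- n_placed + 2L
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next

    # stage 2: remaining isolated dots
    while (ok && n_placed < n) {
      placed <- FALSE
      for (attempt in seq_len(config$max_attempts)) {
        pnt <- runif_disc(R)
        if (n_placed > 0) {
          prev <- dots[seq_len(n_placed), , drop = FALSE]
          if (any((prev[, 1] - pnt[1])^2 + (prev[, 2] - pnt[2])^2 < sep^2)) next
        }
        if (n_pairs > 0) {
          bad <- FALSE
          for (s in segs) {
            if (point_segment_distance(pnt, s$a, s$b) < sep) { bad <- TRUE; break }
          }
          if (bad) next
        }
        dots[n_placed + 1L, ] <- pnt
        n_placed <- n_placed + 1L
        placed <- TRUE
        break
      }
      if (!placed) ok <- FALSE
    }
    if (!ok) next

    connectors <- if (n_pairs > 0) {
      data.frame(
        i = vapply(segs, `[[`, integer(1), "i"),
        j = vapply(segs, `[[`, integer(1), "j")
      )
    } else {
      data.frame(i = integer(0), j = integer(0))
    }
    pat <- structure(
      list(
        dots = data.frame(x = dots[, 1], y = dots[, 2],
                          polarity = sample_polarity(n)),
        connectors = connectors,
        config = config,
        kind = if (n_pairs > 0) "connected" else "isolated"
      ),
      class = "dot_pattern"
    )
    return(pat)
  }
  infeasible_error(
    if (n_pairs > 0) "non-overlapping dots / non-crossing connectors"
    else "minimum dot separation",
    sprintf("pattern generation (N = %d, %d restarts exhausted)",
            n, config$max_restarts)
  )
}

#' Validate every geometric invariant of a dot pattern
#'
#' Checks, without ever raising: minimum pairwise dot separation; connector
#' lengths within range; no connector pair crossing or touching; clearance of
#' non-endpoint dots from every connector; near-equal polarity counts; all
#' dots inside the field radius; each dot used by at most one connector.
#'
#' @param pattern A `dot_pattern`.
#' @return A data frame with one row per check (`check`, `pass`, `detail`)
#'   and attribute `ok` (`TRUE` when all checks passed).
#' @export
validate_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "dot_pattern"))
  cfg <- pattern$config
  d <- pattern$dots
  cn <- pattern$connectors
  n <- nrow(d)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }

  # pairwise separation
  if (n >= 2) {
    dm <- as.matrix(stats::dist(d[, c("x", "y")]))
    diag(dm) <- Inf
    bad <- which(dm < cfg$min_separation, arr.ind = TRUE)
    add("min_separation", nrow(bad) == 0,
        if (nrow(bad)) paste0("dots ", paste(unique(pmin(bad[, 1], bad[, 2])), collapse = ","))
        else sprintf("min distance %.4f", min(dm)))
  } else {
    add("min_separation", TRUE, "single dot")
  }

  # field extent
  r <- sqrt(d$x^2 + d$y^2)
  add("field_radius", all(r <= cfg$field_radius + 1e-9),
      sprintf("max radius %.4f", max(r)))

  # polarity balance
  nw <- sum(d$polarity == "white")
  add("polarity_balance", abs(nw - (n - nw)) <= 1,
      sprintf("%d white / %d black", nw, n - nw))

  if (nrow(cn) > 0) {
    ends <- lapply(seq_len(nrow(cn)), function(k) {
      list(a = c(d$x[cn$i[k]], d$y[cn$i[k]]), b = c(d$x[cn$j[k]], d$y[cn$j[k]]))
    })
    lens <- vapply(ends, function(e) sqrt(sum((e$a - e$b)^2)), numeric(1))
    in_range <- lens >= cfg$connector_length_range[1] - 1e-9 &
      lens <= cfg$connector_length_range[2] + 1e-9
    add("connector_length", all(in_range),
        if (all(in_range)) sprintf("lengths %.3f-%.3f", min(lens), max(lens))
        else paste0("connectors ", paste(which(!in_range), collapse = ",")))

    # at most one connector per dot
    idx <- c(cn$i, cn$j)
    add("one_connector_per_dot", !anyDuplicated(idx),
        if (anyDuplicated(idx)) paste0("dots ", paste(idx[duplicated(idx)], collapse = ",")) else "")

    # no crossing / touching
    cross <- character(0)
    if (nrow(cn) >= 2) {
      for (p in 1:(nrow(cn) - 1)) for (q in (p + 1):nrow(cn)) {
        if (segments_intersect(ends[[p]]$a, ends[[p]]$b, ends[[q]]$a, ends[[q]]$b))
          cross <- c(cross, sprintf("%d-%d", p, q))
      }
    }
    add("no_crossing", length(cross) == 0, paste(cross, collapse = ","))

    # clearance of non-endpoint dots from connectors
    other <- setdiff(seq_len(n), idx)
    viol <- character(0)
    if (length(other)) {
      pts <- as.matrix(d[other, c("x", "y")])
      for (k in seq_along(ends)) {
        dd <- points_segment_distance(pts, ends[[k]]$a, ends[[k]]$b)
        if (any(dd < cfg$min_separation - 1e-9))
          viol <- c(viol, sprintf("connector %d: dots %s", k,
                                  paste(other[dd < cfg$min_separation - 1e-9], collapse = ",")))
      }
    }
    add("dot_connector_clearance", length(viol) == 0, paste(viol, collapse = "; "))
  }

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}

#' @export
print.dot_pattern <- function(x, ...) {
  cat(sprintf("<dot_pattern> %s, N = %d, %d connector(s)\n",
              x$kind, nrow(x$dots), nrow(x$connectors)))
  invisible(x)
}

#' Export a dot pattern to JSON
#'
#' Writes `{kind, config, dots:[{x,y,polarity}], connectors:[{i,j}]}` with
#' coordinates in degrees at six decimal places. Indices are 1-based.
#'
#' @param pattern A `dot_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_json <- function(pattern, path) {
  stopifnot(inherits(pattern, "dot_pattern"))
  cfg <- pattern$config
  cfg$seed <- if (is.null(cfg$seed)) NA else cfg$seed
  obj <- list(
    kind = pattern$kind,
    config = unclass(cfg),
    dots = data.frame(
      x = round(pattern$dots$x, 6),
      y = round(pattern$dots$y, 6),
      polarity = pattern$dots$polarity
    ),
    connectors = pattern$connectors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 6, na = "null")
  invisible(path)
}

#' Export a dot pattern to SVG
#'
#' Simple vector rendering at 100 px per degree: dots as filled circles on a
#' mid-grey background, connectors as lines of the configured width.
#'
#' @param pattern A `dot_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_svg <- function(pattern, path) {
  stopifnot(inherits(pattern, "dot_pattern"))
  cfg <- pattern$config
  px <- 100
  half <- cfg$field_radius + cfg$dot_diameter
  size <- 2 * half * px
  tx <- function(v) (v + half) * px
  ty <- function(v) (half - v) * px
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
    size, size, size, size
  ), sprintf('<rect width="%.0f" height="%.0f" fill="#808080"/>', size, size))
  d <- pattern$dots
  cn <- pattern$connectors
  if (nrow(cn)) {
    lines <- c(lines, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="black" stroke-width="%.2f"/>',
      tx(d$x[cn$i]), ty(d$y[cn$i]), tx(d$x[cn$j]), ty(d$y[cn$j]),
      cfg$connector_width * px
    ))
  }
  lines <- c(lines, sprintf(
    '<circle cx="%.2f" cy="%.2f" r="%.2f" fill="%s"/>',
    tx(d$x), ty(d$y), cfg$dot_diameter / 2 * px, d$polarity
  ), "</svg>")
  writeLines(lines, path)
  invisible(path)
}
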