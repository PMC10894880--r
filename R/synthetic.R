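# Synthetic multi-slide cohort generator. Emulates, at desk scale, the
# structure of an H&E WSI cohort: cases with several slides, slides with
# many tiles, class-dependent patch-likelihood distributions (Beta laws), a
# binary recurrence outcome that shifts those laws, and binary pathological
# findings planted on designated fusion-feature bins. Every downstream
# stage of the pipeline is testable against this generator without any
# clinical data.

#' Specification of a synthetic cohort
#'
#' @param n_cases_per_class Named integer vector: cases per class. Names are
#'   the class labels; the first class is the reference ("positive") class
#'   whose likelihood the Beta laws describe.
#' @param slides_per_case Integer range `c(min, max)`; slides per case drawn
#'   uniformly.
#' @param tiles_per_slide Integer range `c(min, max)`; kept tiles per slide
#'   drawn uniformly.
#' @param likelihood_law Named list, one entry per class: either
#'   `c(shape1, shape2)` of the Beta law of a tile's positive-class
#'   likelihood, or a single value in `[0, 1]` for a point mass
#'   (variance-zero law).
#' @param texture_law Named list, one entry per class, each a list with
#'   `blob_density` (expected nuclei-like blobs per tile), `stripe_freq`
#'   (eosin stripe cycles per tile; 0 for none) and `stain_mix`
#'   (`c(hematoxylin, eosin)` concentration weights).
#' @param recurrence_rate Probability a case is recurrent (default 0.2,
#'   matching the 14--20% recurrence range reported for these cysts).
#' @param recurrence_effect Additive shift of the Beta mean for recurrent
#'   cases (concentration preserved; mean clamped to (0.02, 0.98)).
#' @param findings_model Named list, one entry per finding, each a list with
#'   `prevalence` in `[0, 1]`, `token` (the likelihood bin whose histogram
#'   mass drives the finding, e.g. `"0.39"`), and `slope` (log-odds per SD
#'   of that feature; default 3).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cases_per_class = c(okc = 20, ooc = 20),
                           slides_per_case = c(2L, 4L),
                           tiles_per_slide = c(50L, 200L),
                           likelihood_law = NULL,
                           texture_law = NULL,
                           recurrence_rate = 0.2,
                           recurrence_effect = 0.15,
                           findings_model = list(),
                           seed = 1L) {
  classes <- names(n_cases_per_class)
  if (is.null(classes) || any(!nzchar(classes))) {
    stopf("n_cases_per_class must be a named vector of class counts")
  }
  if (any(n_cases_per_class < 1)) stopf("all class counts must be >= 1")
  if (any(slides_per_case < 1) || any(tiles_per_slide < 1)) {
    stopf("all counts must be >= 1")
  }
  if (is.null(likelihood_law)) {
    defaults <- list(c(8, 2), c(2, 8), c(4, 4))
    likelihood_law <- stats::setNames(
      defaults[pmin(seq_along(classes), 3)], classes)
  }
  for (cl in classes) {
    law <- likelihood_law[[cl]]
    if (is.null(law)) stopf("no likelihood law for class '%s'", cl)
    if (length(law) == 1) {
      if (law < 0 || law > 1) stopf("point-mass likelihood must lie in [0, 1]")
    } else if (length(law) != 2 || any(!is.finite(law)) || any(law <= 0)) {
      stopf("Beta parameters for class '%s' must be two positive numbers", cl)
    }
  }
  if (is.null(texture_law)) {
    defaults <- list(
      list(blob_density = 45, stripe_freq = 0, stain_mix = c(1.0, 0.5)),
      list(blob_density = 6, stripe_freq = 6, stain_mix = c(0.45, 1.0)),
      list(blob_density = 20, stripe_freq = 3, stain_mix = c(0.8, 0.8)))
    texture_law <- stats::setNames(
      defaults[pmin(seq_along(classes), 3)], classes)
  }
  if (recurrence_rate < 0 || recurrence_rate > 1) {
    stopf("recurrence_rate must lie in [0, 1]")
  }
  for (f in names(findings_model)) {
    fm <- findings_model[[f]]
    if (is.null(fm$prevalence) || fm$prevalence < 0 || fm$prevalence > 1) {
      stopf("finding '%s' needs a prevalence in [0, 1]", f)
    }
  }
  structure(list(n_cases_per_class = n_cases_per_class,
                 slides_per_case = as.integer(slides_per_case),
                 tiles_per_slide = as.integer(tiles_per_slide),
                 likelihood_law = likelihood_law,
                 texture_law = texture_law,
                 recurrence_rate = recurrence_rate,
                 recurrence_effect = recurrence_effect,
                 findings_model = findings_model,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Uniform draw from an integer range, safe for degenerate ranges (R's
# sample(n, 1) would otherwise sample from 1:n).
sample_range <- function(range) {
  if (range[1] >= range[2]) return(range[1])
  sample(range[1]:range[2], 1)
}

# Draw n likelihoods from a class law, shifted for recurrent cases by
# moving the Beta mean while preserving its concentration.
draw_likelihoods <- function(law, n, shift = 0) {
  if (length(law) == 1) {
    return(rep(min(max(law + shift, 0), 1), n))
  }
  a <- law[1]; b <- law[2]
  if (shift != 0) {
    kappa <- a + b
    m <- min(max(a / kappa + shift, 0.02), 0.98)
    a <- m * kappa
    b <- (1 - m) * kappa
  }
  stats::rbeta(n, a, b)
}

#' Generate a synthetic patch-likelihood table and cohort registry
#'
#' Samples, per tile, the positive-class likelihood from the class's Beta
#' law (shifted for recurrent cases); remaining classes share the
#' complement uniformly so every row lies on the probability simplex.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (the patch-likelihood table: `case_id`,
#'   `slide_id`, `grid_col`, `grid_row`, `p_<class>` columns, `label`) and
#'   `cohort` (`case_id`, `class_label`, `recurrence`, `n_slides`).
#' @export
generate_likelihood_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- names(spec$n_cases_per_class)
  K <- length(classes)
  with_seed(spec$seed, {
    rows <- list()
    cohort <- list()
    ci <- 0
    for (cl in classes) {
      for (i in seq_len(spec$n_cases_per_class[[cl]])) {
        ci <- ci + 1
        case_id <- sprintf("case%04d", ci)
        rec <- stats::rbinom(1, 1, spec$recurrence_rate)
        ns <- sample_range(spec$slides_per_case)
        for (s in seq_len(ns)) {
          slide_id <- sprintf("%s_s%02d", case_id, s)
          nt <- sample_range(spec$tiles_per_slide)
          q <- draw_likelihoods(spec$likelihood_law[[cl]], nt,
                                shift = if (rec == 1) spec$recurrence_effect else 0)
          probs <- if (K == 1) {
            matrix(1, nt, 1)     # degenerate one-class simplex
          } else {
            cbind(q, matrix((1 - q) / (K - 1), nt, K - 1))
          }
          colnames(probs) <- classes
          ncol_grid <- ceiling(sqrt(nt))
          rows[[slide_id]] <- data.frame(
            case_id = case_id, slide_id = slide_id,
            grid_col = (seq_len(nt) - 1) %% ncol_grid,
            grid_row = (seq_len(nt) - 1) %/% ncol_grid,
            stats::setNames(as.data.frame(probs), paste0("p_", classes)),
            label = classes[max.col(probs, ties.method = "first")],
            stringsAsFactors = FALSE)
        }
        cohort[[case_id]] <- data.frame(case_id = case_id, class_label = cl,
                                        recurrence = rec, n_slides = ns,
                                        stringsAsFactors = FALSE)
      }
    }
    list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
         cohort = do.call(rbind, c(cohort, make.row.names = FALSE)))
  })
}

# Published H&E optical-density stain directions (unit norm).
he_stain_defaults <- function() {
  m <- cbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

# Rotate a unit vector by a random angle <= max_deg toward a random
# direction orthogonal to it.
jitter_stain_vector <- function(v, max_deg) {
  u <- stats::rnorm(3)
  u <- u - sum(u * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(v)
  u <- u / nu
  a <- stats::runif(1, 0, max_deg * pi / 180)
  w <- cos(a) * v + sin(a) * u
  w <- pmax(w, 0)              # stain OD directions are non-negative
  w / sqrt(sum(w^2))
}

#' Generate one synthetic H&E-like tile
#'
#' Composes two synthetic stain concentration fields -- a hematoxylin-like
#' field of nuclei-scale blobs and an eosin-like field of smooth background
#' plus optional stripes -- and mixes them through Beer-Lambert optical
#' density with the published H&E stain directions (per-tile angular jitter
#' at most 5 degrees), so that Macenko estimation has a recoverable ground
#' truth.
#'
#' @param texture Texture parameters: `blob_density`, `stripe_freq`,
#'   `stain_mix` (see [synthetic_spec()]).
#' @param seed Integer seed; fixed seed gives identical image bytes.
#' @param size Tile side in pixels (default 512).
#' @param region Optional `c(col0, col1, row0, row1)` fractions of the tile
#'   restricting where blobs are planted (used by localization tests).
#' @return Numeric `size x size x 3` RGB array on the 0..255 scale, with the
#'   jittered stain matrix attached as attribute `"stain_matrix"`.
#' @export
generate_tile_image <- function(texture, seed = 1, size = 512,
                                region = NULL) {
  stopifnot(is.list(texture), length(texture$stain_mix) == 2)
  with_seed(seed, {
    ch <- matrix(0, size, size)          # hematoxylin concentration field
    n_blobs <- stats::rpois(1, texture$blob_density %||% 20)
    r0 <- c(0, 1, 0, 1)
    if (!is.null(region)) r0 <- region
    for (b in seq_len(n_blobs)) {
      cx <- stats::runif(1, r0[1], r0[2]) * size
      cy <- stats::runif(1, r0[3], r0[4]) * size
      sigma <- stats::runif(1, size / 64, size / 32)
      amp <- stats::runif(1, 0.6, 1.2)
      # evaluate the Gaussian only inside a 3-sigma window
      xs <- max(1, floor(cx - 3 * sigma)):min(size, ceiling(cx + 3 * sigma))
      ys <- max(1, floor(cy - 3 * sigma)):min(size, ceiling(cy + 3 * sigma))
      if (!length(xs) || !length(ys)) next
      gx <- exp(-((xs - cx)^2) / (2 * sigma^2))
      gy <- exp(-((ys - cy)^2) / (2 * sigma^2))
      ch[ys, xs] <- ch[ys, xs] + amp * outer(gy, gx)
    }
    ce <- matrix(0.35, size, size)       # eosin concentration field
    sf <- texture$stripe_freq %||% 0
    if (sf > 0) {
      theta <- stats::runif(1, 0, pi)
      phase <- stats::runif(1, 0, 2 * pi)
      xy <- outer(seq_len(size) * sin(theta), rep(1, size)) +
        outer(rep(1, size), seq_len(size) * cos(theta))
      ce <- ce + 0.25 * (1 + sin(2 * pi * sf * xy / size + phase)) / 2
    }
    # nuclei displace eosinophilic cytoplasm: attenuate the eosin field
    # where the blob field is dense, so near-pure-hematoxylin pixels exist
    # and the extreme-angle stain estimate has something to latch onto
    ce <- ce * exp(-1.5 * ch)
    ch <- ch * texture$stain_mix[1]
    ce <- ce * texture$stain_mix[2]
    stains <- he_stain_defaults()
    stains <- cbind(hematoxylin = jitter_stain_vector(stains[, 1], 5),
                    eosin = jitter_stain_vector(stains[, 2], 5))
    od <- cbind(as.vector(ch), as.vector(ce)) %*% t(stains)
    img <- array(255 * 10^(-od), c(size, size, 3))
    img <- img + array(stats::rnorm(length(img), sd = 1.5), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
    attr(img, "stain_matrix") <- stains
    img
  })
}

# Per-case relative frequency of a likelihood token, used to plant findings.
token_frequency <- function(table, cohort, token) {
  decimals <- max(1L, nchar(sub("^[01]\\.?", "", token)))
  classes <- plt_classes(table)
  toks <- discretize(table[[paste0("p_", classes[1])]], decimals)
  vapply(cohort$case_id, function(cid) {
    sel <- table$case_id == cid
    if (!any(sel)) return(0)
    mean(toks[sel] == token)
  }, 0)
}

#' Generate planted binary pathological findings
#'
#' Each finding is drawn from a logistic model on one designated fusion
#' feature: the case-level relative frequency of the finding's likelihood
#' token, standardized, times the configured slope; the intercept is
#' calibrated so the marginal prevalence matches the specification.
#'
#' @param spec A [synthetic_spec()] with a non-empty `findings_model`.
#' @param table,cohort Output of [generate_likelihood_table()].
#' @return Data frame with `case_id` and one 0/1 column per finding.
#' @export
generate_findings <- function(spec, table, cohort) {
  out <- data.frame(case_id = cohort$case_id, stringsAsFactors = FALSE)
  if (!length(spec$findings_model)) return(out)
  with_seed(child_seed(spec$seed, "findings"), {
    for (f in names(spec$findings_model)) {
      fm <- spec$findings_model[[f]]
      if (fm$prevalence == 0) { out[[f]] <- 0L; next }
      if (fm$prevalence == 1) { out[[f]] <- 1L; next }
      slope <- fm$slope %||% 3
      z <- token_frequency(table, cohort, fm$token %||% "0.5")
      z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
      a <- stats::uniroot(function(a0) mean(stats::plogis(a0 + slope * z)) -
                            fm$prevalence, c(-50, 50))$root
      out[[f]] <- stats::rbinom(nrow(out), 1, stats::plogis(a + slope * z))
    }
  })
  out
}

#' Write a full synthetic cohort to disk
#'
#' Produces the on-disk interchange layout: one PNG per tile at
#' `<case>/<slide>/<col>_<row>.png`, a `labels.csv`
#' (`case_id,slide_id,class_label,recurrence,split`) and a `findings.csv`
#' (one binary column per finding).
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @param tile_size Side of the generated tiles (default 512; tests may
#'   shrink it).
#' @return Invisibly, the list from [generate_likelihood_table()] plus
#'   `findings` and `dir`.
#' @export
generate_cohort <- function(spec, out_dir, tile_size = 512) {
  gen <- generate_likelihood_table(spec)
  findings <- generate_findings(spec, gen$table, gen$cohort)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create directory '%s'", out_dir)
  for (i in seq_len(nrow(gen$table))) {
    row <- gen$table[i, ]
    cl <- gen$cohort$class_label[gen$cohort$case_id == row$case_id]
    d <- file.path(out_dir, row$case_id, row$slide_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    tile <- generate_tile_image(
      spec$texture_law[[cl]],
      seed = child_seed(spec$seed, row$slide_id, row$grid_col, row$grid_row),
      size = tile_size)
    write_tile_png(tile, file.path(d, sprintf("%d_%d.png", row$grid_col,
                                              row$grid_row)))
  }
  labels <- merge(unique(gen$table[c("case_id", "slide_id")]),
                  gen$cohort[c("case_id", "class_label", "recurrence")],
                  by = "case_id", sort = TRUE)
  labels$split <- NA_character_
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(findings, file.path(out_dir, "findings.csv"),
                   row.names = FALSE)
  invisible(c(gen, list(findings = findings, dir = out_dir)))
}
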