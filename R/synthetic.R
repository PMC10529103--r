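# Synthetic sketch generators. Two corpora are emulated so the whole
# pipeline is testable without any proprietary or external data:
#  * an HTP-like two-class set: white background, dark pencil strokes, each
#    image containing a procedurally drawn house, tree and person. The
#    depressed class draws from darker stroke-intensity distributions and
#    higher probabilities for depressive motifs (falling rain, cracked
#    walls, bare branches, trembling lines);
#  * a many-class glyph corpus drawn white-on-black, exercising the color
#    inversion required before pre-training.

# ---- drawing primitives (ink in [0,1] on an ink matrix) -------------------

stamp_points <- function(ink, xs, ys, width, intensity) {
  side <- nrow(ink)
  r <- max(0, round((width - 1) / 2))
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 0.5, , drop = FALSE]
  xi0 <- round(xs); yi0 <- round(ys)
  for (o in seq_len(nrow(offs))) {
    xi <- xi0 + offs$dx[o]; yi <- yi0 + offs$dy[o]
    ok <- xi >= 1 & xi <= side & yi >= 1 & yi <= side
    if (!any(ok)) next
    idx <- cbind(yi[ok], xi[ok])
    ink[idx] <- pmax(ink[idx], intensity)
  }
  ink
}

line_points <- function(x0, y0, x1, y1, wobble = 0) {
  n <- max(2, ceiling(max(abs(x1 - x0), abs(y1 - y0))) + 1)
  t <- seq(0, 1, length.out = n)
  xs <- x0 + t * (x1 - x0)
  ys <- y0 + t * (y1 - y0)
  if (wobble > 0) {
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- wobble * len
    nx <- -(y1 - y0) / max(len, 1); ny <- (x1 - x0) / max(len, 1)
    dev <- amp * sin(t * stats::runif(1, 2, 5) * pi + ph) + stats::rnorm(n, sd = amp / 3)
    xs <- xs + nx * dev; ys <- ys + ny * dev
  }
  list(x = xs, y = ys)
}

draw_line <- function(ink, x0, y0, x1, y1, width, intensity, wobble = 0) {
  p <- line_points(x0, y0, x1, y1, wobble)
  stamp_points(ink, p$x, p$y, width, intensity)
}

draw_circle <- function(ink, cx, cy, radius, width, intensity, from = 0, to = 2 * pi) {
  n <- max(8, ceiling(2 * pi * radius))
  t <- seq(from, to, length.out = n)
  stamp_points(ink, cx + radius * cos(t), cy + radius * sin(t), width, intensity)
}

# ---- HTP-like two-class corpus --------------------------------------------

#' Parameters for the HTP-like generator
#'
#' Defaults encode the study conditions of the screening task: a class
#' imbalance of 319/1615 (about 19.8% depressed), white 512 x 512 canvases,
#' and a class-conditional style signal. The signal has two components:
#' stroke darkness (mean ink intensity `darkness_base +/- darkness_margin/2`,
#' the depressed class drawing darker) and motif probabilities (rain dots,
#' wall cracks, bare branches, and how often the scene is drawn with smooth,
#' untrembling lines).
#'
#' @param n_samples number of sketches.
#' @param class1_fraction fraction of depressed-class sketches.
#' @param canvas_side canvas side in pixels (>= 96).
#' @param stroke_width_range min/max stroke width in pixels. The default band
#'   is narrow, as for a single pencil type: stroke darkness (pressure), not
#'   width, is the class marker, and total-ink statistics confound the two
#'   when strokes are thinner than the model's input resolution.
#' @param darkness_base mean ink intensity midpoint, in (0, 1).
#' @param darkness_margin separation of the class darkness means; 0 removes
#'   the darkness signal.
#' @param jitter standard deviation of per-sketch darkness jitter.
#' @param motif_probs list with elements `normal` and `depressed`, each a
#'   named vector with probabilities `rain`, `cracks`, `bare`, `smooth`.
#' @param seed master seed; generation is a pure function of the parameters.
#' @return An object of class `htp_gen_params`.
#' @export
htp_gen_params <- function(n_samples = 400, class1_fraction = 319 / 1615,
                           canvas_side = 512, stroke_width_range = c(2.5, 3.5),
                           darkness_base = 0.5, darkness_margin = 0.3,
                           jitter = 0.08,
                           motif_probs = list(
                             normal = c(rain = 0.05, cracks = 0.05, bare = 0.10, smooth = 0.90),
                             depressed = c(rain = 0.60, cracks = 0.50, bare = 0.70, smooth = 0.25)),
                           seed = 0) {
  if (class1_fraction <= 0 || class1_fraction >= 1) stopf("class1_fraction must be in (0, 1)")
  if (canvas_side < 96) stopf("canvas too small for motifs (need >= 96 px)")
  if (darkness_margin < 0) stopf("darkness_margin must be non-negative")
  structure(list(n_samples = as.integer(n_samples), class1_fraction = class1_fraction,
                 canvas_side = as.integer(canvas_side),
                 stroke_width_range = stroke_width_range,
                 darkness_base = darkness_base, darkness_margin = darkness_margin,
                 jitter = jitter, motif_probs = motif_probs, seed = as.integer(seed)),
            class = "htp_gen_params")
}

draw_house <- function(ink, cx, cy, size, w, int, wob, cracks) {
  x0 <- cx - size / 2; x1 <- cx + size / 2
  y0 <- cy - size / 2; y1 <- cy + size / 2
  ink <- draw_line(ink, x0, y0, x1, y0, w, int, wob)
  ink <- draw_line(ink, x0, y1, x1, y1, w, int, wob)
  ink <- draw_line(ink, x0, y0, x0, y1, w, int, wob)
  ink <- draw_line(ink, x1, y0, x1, y1, w, int, wob)
  ink <- draw_line(ink, x0 - size * 0.08, y0, cx, y0 - size * 0.45, w, int, wob)
  ink <- draw_line(ink, cx, y0 - size * 0.45, x1 + size * 0.08, y0, w, int, wob)
  dx <- cx + stats::runif(1, -0.15, 0.15) * size
  ink <- draw_line(ink, dx - size * 0.12, y1, dx - size * 0.12, y1 - size * 0.35, w, int, wob)
  ink <- draw_line(ink, dx + size * 0.12, y1, dx + size * 0.12, y1 - size * 0.35, w, int, wob)
  ink <- draw_line(ink, dx - size * 0.12, y1 - size * 0.35, dx + size * 0.12, y1 - size * 0.35, w, int, wob)
  if (cracks) {
    for (k in 1:2) {
      px <- stats::runif(1, x0 + size * 0.1, x1 - size * 0.3)
      py <- stats::runif(1, y0 + size * 0.1, y0 + size * 0.4)
      for (s in 1:4) {
        nx <- px + stats::runif(1, 0.02, 0.1) * size * sample(c(-1, 1), 1)
        ny <- py + stats::runif(1, 0.05, 0.12) * size
        ink <- draw_line(ink, px, py, nx, ny, max(1, w - 1), int, 0)
        px <- nx; py <- ny
      }
    }
  }
  ink
}

draw_tree <- function(ink, cx, base_y, height, w, int, wob, bare) {
  top <- base_y - height
  ink <- draw_line(ink, cx - w, base_y, cx - w, top + height * 0.35, w, int, wob)
  ink <- draw_line(ink, cx + w, base_y, cx + w, top + height * 0.35, w, int, wob)
  n_br <- if (bare) sample(7:9, 1) else sample(3:4, 1)
  for (b in seq_len(n_br)) {
    ang <- stats::runif(1, pi / 6, pi / 2.2) * sample(c(-1, 1), 1)
    y_at <- top + height * stats::runif(1, 0.1, 0.4)
    len <- height * stats::runif(1, 0.25, 0.45)
    ex <- cx + len * sin(ang); ey <- y_at - len * cos(ang) * 0.6
    ink <- draw_line(ink, cx, y_at, ex, ey, max(1, w - 1), int, wob)
    if (bare) {
      ink <- draw_line(ink, ex, ey, ex + len * 0.5 * sin(ang + 0.5),
                       ey - len * 0.35, max(1, w - 1), int, wob)
      ink <- draw_line(ink, ex, ey, ex + len * 0.5 * sin(ang - 0.5),
                       ey - len * 0.3, max(1, w - 1), int, wob)
    }
  }
  if (!bare) {
    for (k in 1:2) {
      ink <- draw_circle(ink, cx + stats::runif(1, -0.2, 0.2) * height,
                         top + height * stats::runif(1, 0.05, 0.3),
                         height * stats::runif(1, 0.12, 0.2), max(1, w - 1), int)
    }
  }
  ink
}

draw_person <- function(ink, cx, base_y, h, w, int, wob) {
  head_r <- h * 0.16
  head_y <- base_y - h + head_r
  ink <- draw_circle(ink, cx, head_y, head_r, max(1, w - 1), int)
  ink <- draw_line(ink, cx, head_y + head_r, cx, base_y - h * 0.35, w, int, wob)
  arm_y <- head_y + head_r + h * 0.15
  ink <- draw_line(ink, cx, arm_y, cx - h * 0.25, arm_y + h * 0.15, max(1, w - 1), int, wob)
  ink <- draw_line(ink, cx, arm_y, cx + h * 0.25, arm_y + h * 0.15, max(1, w - 1), int, wob)
  hip <- base_y - h * 0.35
  ink <- draw_line(ink, cx, hip, cx - h * 0.18, base_y, max(1, w - 1), int, wob)
  ink <- draw_line(ink, cx, hip, cx + h * 0.18, base_y, max(1, w - 1), int, wob)
  ink
}

draw_rain <- function(ink, side, w, int) {
  n <- sample(15:30, 1)
  xs <- stats::runif(n, 1, side)
  ys <- stats::runif(n, 1, side * 0.45)
  for (i in seq_len(n))
    ink <- draw_line(ink, xs[i], ys[i], xs[i] - 2, ys[i] + stats::runif(1, 4, 10),
                     max(1, w - 1), int)
  ink
}

gen_htp_one <- function(params, label, seed) {
  with_seed(seed, {
    side <- params$canvas_side
    ink <- matrix(0, side, side)
    mp <- params$motif_probs[[if (label == 1) "depressed" else "normal"]]
    dmean <- params$darkness_base + (if (label == 1) 0.5 else -0.5) * params$darkness_margin
    int <- clamp(stats::rnorm(1, dmean, params$jitter), 0.05, 0.98)
    w <- stats::runif(1, params$stroke_width_range[1], params$stroke_width_range[2])
    smooth <- stats::runif(1) < mp["smooth"]
    wob <- if (smooth) 0 else stats::runif(1, 0.01, 0.035)
    cracks <- stats::runif(1) < mp["cracks"]
    bare <- stats::runif(1) < mp["bare"]
    rain <- stats::runif(1) < mp["rain"]
    ground <- side * stats::runif(1, 0.78, 0.9)
    ink <- draw_house(ink, side * stats::runif(1, 0.24, 0.32), ground - side * 0.14,
                      side * stats::runif(1, 0.2, 0.28), w, int, wob, cracks)
    ink <- draw_tree(ink, side * stats::runif(1, 0.68, 0.8), ground,
                     side * stats::runif(1, 0.3, 0.42), w, int, wob, bare)
    ink <- draw_person(ink, side * stats::runif(1, 0.45, 0.55), ground,
                       side * stats::runif(1, 0.16, 0.24), w, int, wob)
    if (rain) ink <- draw_rain(ink, side, w, int)
    px <- 255 * (1 - ink)
    sketch_image(round(px), background = "white", label = label)
  })
}

#' Generate an HTP-like two-class sketch corpus
#'
#' Each sketch contains a procedurally drawn house, tree and person on a
#' white canvas; the depressed class (label 1) draws from darker stroke
#' distributions and higher depressive-motif probabilities (see
#' [htp_gen_params()]). Exactly `round(n_samples * class1_fraction)` sketches
#' carry label 1; output is bitwise reproducible for a fixed seed.
#'
#' @param params an [htp_gen_params()].
#' @return A labeled [sketch_dataset()] with white-background images.
#' @examples
#' ds <- generate_htp_like(htp_gen_params(n_samples = 4, canvas_side = 128))
#' table(ds$labels)
#' @export
generate_htp_like <- function(params = htp_gen_params()) {
  stopifnot(inherits(params, "htp_gen_params"))
  n <- params$n_samples
  n1 <- round(n * params$class1_fraction)
  labels <- with_seed(derive_seed(params$seed, 23),
                      sample(c(rep(1L, n1), rep(0L, n - n1))))
  images <- lapply(seq_len(n), function(i)
    gen_htp_one(params, labels[i], derive_seed(params$seed, 29, i)))
  sketch_dataset(images, labels, num_class = 2L)
}

# ---- many-class glyph corpus ----------------------------------------------

glyph_families <- list(
  circle = function(s) list(circ = c(0, 0, 0.38)),
  square = function(s) list(poly = rbind(c(-.35, -.35), c(.35, -.35), c(.35, .35), c(-.35, .35), c(-.35, -.35))),
  triangle = function(s) list(poly = rbind(c(0, -.4), c(.38, .3), c(-.38, .3), c(0, -.4))),
  star = function(s) {
    a <- seq(0, 4 * pi, length.out = 6) + pi / 2
    list(poly = cbind(0.4 * cos(a), -0.4 * sin(a)))
  },
  spiral = function(s) {
    t <- seq(0, 5 * pi, length.out = 120)
    list(path = cbind(0.4 * t / (5 * pi) * cos(t), 0.4 * t / (5 * pi) * sin(t)))
  },
  cross = function(s) list(poly = rbind(c(-.35, 0), c(.35, 0)), poly2 = rbind(c(0, -.35), c(0, .35))),
  grid = function(s) {
    segs <- list()
    for (v in c(-.2, 0, .2)) {
      segs[[length(segs) + 1]] <- rbind(c(v, -.35), c(v, .35))
      segs[[length(segs) + 1]] <- rbind(c(-.35, v), c(.35, v))
    }
    names(segs) <- paste0("poly", seq_along(segs))
    segs
  },
  zigzag = function(s) {
    x <- seq(-.38, .38, length.out = 9)
    y <- rep(c(-.2, .2), length.out = 9)
    list(path = cbind(x, y))
  },
  wave = function(s) {
    x <- seq(-.4, .4, length.out = 80)
    list(path = cbind(x, 0.2 * sin(x * 12)))
  },
  diamond = function(s) list(poly = rbind(c(0, -.4), c(.3, 0), c(0, .4), c(-.3, 0), c(0, -.4))),
  hexagon = function(s) {
    a <- seq(0, 2 * pi, length.out = 7)
    list(poly = cbind(0.38 * cos(a), 0.38 * sin(a)))
  },
  arcs = function(s) list(circ = c(-0.12, 0, 0.3, 0.4 * pi, 1.6 * pi),
                          circ2 = c(0.12, 0, 0.3, 1.4 * pi, 2.6 * pi))
)

#' Parameters for the many-class glyph generator
#'
#' @param n_classes number of glyph families to draw from (at most
#'   `length(glyph_families)` = 12).
#' @param n_train,n_val,n_test per-class sample counts.
#' @param canvas_side canvas side in pixels.
#' @param stroke_width stroke width in pixels.
#' @param seed master seed.
#' @return An object of class `qd_gen_params`.
#' @export
qd_gen_params <- function(n_classes = 10, n_train = 20, n_val = 5, n_test = 5,
                          canvas_side = 128, stroke_width = 3, seed = 0) {
  if (n_classes > length(glyph_families))
    stopf("n_classes exceeds the %d available glyph families", length(glyph_families))
  if (min(n_train, n_val, n_test) < 1) stopf("per-class counts must be >= 1")
  structure(list(n_classes = as.integer(n_classes), n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 canvas_side = as.integer(canvas_side), stroke_width = stroke_width,
                 seed = as.integer(seed)),
            class = "qd_gen_params")
}

gen_glyph_one <- function(params, class_id, seed) {
  with_seed(seed, {
    side <- params$canvas_side
    ink <- matrix(0, side, side)
    fam <- glyph_families[[class_id + 1]](side)
    sc <- side * stats::runif(1, 0.8, 1.1)
    cx <- side / 2 + stats::rnorm(1, sd = side * 0.04)
    cy <- side / 2 + stats::rnorm(1, sd = side * 0.04)
    rot <- stats::rnorm(1, sd = 0.15)
    R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
    for (nm in names(fam)) {
      el <- fam[[nm]]
      if (startsWith(nm, "circ")) {
        ctr <- R %*% el[1:2]
        from <- if (length(el) >= 5) el[4] else 0
        to <- if (length(el) >= 5) el[5] else 2 * pi
        ink <- draw_circle(ink, cx + ctr[1] * sc, cy + ctr[2] * sc, el[3] * sc,
                           params$stroke_width, 1, from + rot, to + rot)
      } else {
        pts <- el %*% t(R) * sc
        for (i in seq_len(nrow(pts) - 1))
          ink <- draw_line(ink, cx + pts[i, 1], cy + pts[i, 2],
                           cx + pts[i + 1, 1], cy + pts[i + 1, 2],
                           params$stroke_width, 1)
      }
    }
    sketch_image(round(255 * ink), background = "black", label = class_id)
  })
}

#' Generate a many-class white-on-black glyph corpus
#'
#' A desk-scale stand-in for a large sketch pre-training corpus: each class is
#' a distinct parametric glyph family (polygons, spirals, grids, arcs, ...)
#' drawn in white on a black background with per-sample jitter in position,
#' scale and rotation. The background flag is `"black"`, so the pre-training
#' pipeline must color-invert these images.
#'
#' @param params a [qd_gen_params()].
#' @return A labeled [sketch_dataset()] with `split` assignments
#'   (`"train"`/`"val"`/`"test"`).
#' @export
generate_quickdraw_like <- function(params = qd_gen_params()) {
  stopifnot(inherits(params, "qd_gen_params"))
  per <- params$n_train + params$n_val + params$n_test
  split1 <- c(rep("train", params$n_train), rep("val", params$n_val), rep("test", params$n_test))
  labels <- rep(seq_len(params$n_classes) - 1L, each = per)
  split <- rep(split1, params$n_classes)
  images <- lapply(seq_along(labels), function(i)
    gen_glyph_one(params, labels[i], derive_seed(params$seed, 31, i)))
  sketch_dataset(images, labels, num_class = params$n_classes, split = split)
}

#' Write a dataset as PNG files plus a CSV manifest
#'
#' @param dataset a [sketch_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return Path of the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "sketch") {
  stopifnot(inherits(dataset, "sketch_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  files <- sprintf("%s_%04d.png", prefix, seq_len(n))
  for (i in seq_len(n)) write_sketch(dataset$images[[i]], file.path(dir, files[i]))
  manifest <- data.frame(filename = files, label = dataset$labels,
                         split = dataset$split %||% rep("train", n))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing PNG files and `manifest.csv`.
#' @param background background polarity of the stored images.
#' @return A [sketch_dataset()].
#' @export
read_dataset <- function(dir, background = c("white", "black")) {
  background <- match.arg(background)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(seq_len(nrow(manifest)), function(i)
    read_sketch(file.path(dir, manifest$filename[i]), background = background,
                label = manifest$label[i]))
  sketch_dataset(images, manifest$label, split = manifest$split)
}
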