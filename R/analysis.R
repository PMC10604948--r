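#' Unsigned angle at a vertex
#'
#' Angle in degrees between the rays `v -> a` and `v -> b`, in \[0, 180\].
#'
#' @param a,v,b Numeric `(x, y)` points; `v` is the vertex.
#' @return Degrees.
#' @export
angle_at_vertex <- function(a, v, b) {
  u <- a - v; t <- b - v
  if (all(u == 0) || all(t == 0))
    stop("degenerate geometry: a point coincides with the vertex")
  cs <- sum(u * t) / sqrt(sum(u^2) * sum(t^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Angle between two lines
#'
#' Directed mode: angle between the vectors `p1 -> p2` and `q1 -> q2` in
#' \[0, 180\]. Undirected mode folds the result into \[0, 90\] (line
#' orientation ignored).
#'
#' @param p1,p2,q1,q2 Numeric `(x, y)` points.
#' @param mode `"directed"` or `"undirected"`.
#' @return Degrees, with the mode in attribute `"mode"`.
#' @export
line_angle <- function(p1, p2, q1, q2, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  u <- p2 - p1; t <- q2 - q1
  if (all(u == 0) || all(t == 0)) stop("degenerate geometry: zero-length line")
  cs <- sum(u * t) / sqrt(sum(u^2) * sum(t^2))
  ang <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
  if (mode == "undirected" && ang > 90) ang <- 180 - ang
  structure(ang, mode = mode)
}

#' Compute the seven standard clinical measurements
#'
#' From a [landmark_set]: the angles ANB, SNB, SNA (at nasion), the
#' composite indicators ODI and APDI (sums of inter-plane angles), the
#' facial height index FHI (posterior face height S-Go over anterior face
#' height N-Me) and FMA (angle between the S-N and Go-Gn lines). All plane
#' angles use directed vectors ordered "from X to Y". Every measurement is
#' invariant to rigid motion and uniform scaling of the landmark set.
#'
#' @param landmarks A [landmark_set].
#' @param mode Plane-angle mode passed to [line_angle()].
#' @return Object of class `ceph_measurements`: named list with elements
#'   ANB, SNB, SNA, ODI, APDI, FHI, FMA.
#' @export
compute_measurements <- function(landmarks, mode = "directed") {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$points
  pt <- function(name) p[name, ]
  la <- function(a, b, c, d) as.numeric(line_angle(pt(a), pt(b), pt(c),
                                                   pt(d), mode = mode))
  S <- pt("sella"); N <- pt("nasion"); Me <- pt("menton"); Go <- pt("gonion")
  vals <- list(
    ANB = angle_at_vertex(pt("subspinale"), N, pt("supramentale")),
    SNB = angle_at_vertex(S, N, pt("supramentale")),
    SNA = angle_at_vertex(S, N, pt("subspinale")),
    ODI = la("subspinale", "supramentale", "menton", "gonion") +
      la("posterior_nasal_spine", "anterior_nasal_spine",
         "porion", "orbitale"),
    APDI = la("porion", "orbitale", "nasion", "pogonion") +
      la("nasion", "pogonion", "subspinale", "supramentale") +
      la("porion", "orbitale", "posterior_nasal_spine",
         "anterior_nasal_spine"),
    FHI = sqrt(sum((S - Go)^2)) / sqrt(sum((N - Me)^2)),
    FMA = la("sella", "nasion", "gonion", "gnathion"))
  structure(vals, mode = mode, class = "ceph_measurements")
}

#' @export
print.ceph_measurements <- function(x, ...) {
  v <- unlist(x)
  cat("Clinical measurements:\n")
  for (nmv in names(v))
    cat(sprintf("  %-5s %8.3f%s\n", nmv, v[nmv],
                if (nmv == "FHI") "" else " deg"))
  invisible(x)
}

measurement_names <- function() c("ANB", "SNB", "SNA", "ODI", "APDI",
                                  "FHI", "FMA")

#' Anatomical-type classification rules
#'
#' Loads the per-measurement class criteria (class-1 closed interval plus
#' class-2/class-3 predicates). Two variants ship:
#' \describe{
#'   \item{`corrected`}{a monotone partition: class 1 inside the interval,
#'     the printed class-2/class-3 sides used where they are consistent,
#'     and the inconsistent rows (SNB, ODI, APDI) oriented to complete the
#'     partition.}
#'   \item{`literal`}{the predicates exactly as printed, evaluated
#'     with precedence class 1, then 2, then 3; values satisfying several
#'     predicates are flagged as overlaps, values satisfying none are
#'     unclassifiable.}
#' }
#'
#' @param variant `"corrected"` or `"literal"`.
#' @param path Optional path to an edited rules JSON (defaults to the file
#'   shipped with the package).
#' @return Object of class `classification_rules`.
#' @export
classification_rules <- function(variant = c("corrected", "literal"),
                                 path = NULL) {
  variant <- match.arg(variant)
  if (is.null(path))
    path <- system.file("extdata", "classification_rules.json",
                        package = "cephmark")
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)[[variant]]
  structure(list(variant = variant, rules = rules),
            class = "classification_rules")
}

eval_pred <- function(pred, value) {
  op <- pred$op; thr <- pred$value
  switch(op, lt = value < thr, gt = value > thr,
         stop(sprintf("unknown predicate op '%s'", op)))
}

#' Classify measurements into anatomical types
#'
#' Assigns each of the seven measurements a class in \{1, 2, 3\}: class 1
#' on the closed interval, otherwise by the variant's class-2/class-3
#' predicates. Boundary hits (value exactly on a printed threshold) and
#' predicate overlaps are flagged; under the literal variant a value
#' satisfying no predicate gets class `NA` and an `unclassifiable` flag.
#'
#' @param values A `ceph_measurements` (or named list/vector with the
#'   seven measurements).
#' @param rules A [classification_rules()].
#' @return Data frame (class `ceph_classification`): columns `measurement`,
#'   `value`, `class`, `boundary`, `overlap`, `unclassifiable`, plus the
#'   variant in attribute `"variant"`.
#' @export
classify_measurements <- function(values,
                                  rules = classification_rules()) {
  v <- unlist(values)[measurement_names()]
  if (anyNA(v)) stop("missing measurements: ",
                     paste(measurement_names()[is.na(v)], collapse = ", "))
  rows <- lapply(measurement_names(), function(mn) {
    r <- rules$rules[[mn]]
    x <- v[[mn]]
    in1 <- x >= r$class1$lo && x <= r$class1$hi
    hit2 <- eval_pred(r$class2, x)
    hit3 <- eval_pred(r$class3, x)
    boundary <- x %in% c(r$class1$lo, r$class1$hi, r$class2$value,
                         r$class3$value)
    overlap <- sum(in1, hit2, hit3) > 1
    cls <- if (in1) 1L else if (hit2) 2L else if (hit3) 3L else NA_integer_
    data.frame(measurement = mn, value = unname(x), class = cls,
               boundary = boundary, overlap = overlap,
               unclassifiable = is.na(cls), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "variant") <- rules$variant
  class(out) <- c("ceph_classification", "data.frame")
  out
}

#' Classification accuracy against ground truth
#'
#' Percentage of images whose predicted class matches the ground-truth
#' class, per measurement, plus the mean across the seven measurements.
#'
#' @param predicted,truth Lists of `ceph_classification` objects (paired
#'   by position).
#' @return List with `per_measurement` (named percentages) and `mean`.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth lists differ in length")
  pm <- vapply(measurement_names(), function(mn) {
    ok <- mapply(function(p, t) {
      cp <- p$class[p$measurement == mn]
      ct <- t$class[t$measurement == mn]
      !is.na(cp) && !is.na(ct) && cp == ct
    }, predicted, truth)
    100 * mean(ok)
  }, 0)
  list(per_measurement = pm, mean = mean(pm))
}
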