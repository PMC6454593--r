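#' @title The virtual gender model
#'
#' @description
#' Clinical trial registries record the sex eligibility of a study as one of
#' `Male`, `Female` or `All`, which cannot express transgender recruitment
#' requirements. The virtual gender model extends these conventional options
#' with a transgender axis. A requirement is a pair of components, a
#' *transgender* component and a *biological* component, each one of
#' `MALE`, `FEMALE`, `ALL` or `NONE` (absent). All purely biological
#' requirements collapse into the single rendered type `"Biological"`, so the
#' model has exactly 13 renderable types: 3 transgender components x 4
#' biological components, plus `"Biological"`.
#'
#' Evidence found in text is expressed in *composite* gender labels (six of
#' them: `{TRANSGENDER, BIOLOGICAL} x {MALE, FEMALE, ALL}`), which split into
#' the four *meta* gender types (`TRANSGENDER_MALE`, `TRANSGENDER_FEMALE`,
#' `BIOLOGICAL_MALE`, `BIOLOGICAL_FEMALE`) used by the summarizer.
#'
#' @name gender_model
NULL

#' Composite gender labels and meta gender types
#'
#' `composite_genders()` returns the six composite labels; `meta_genders()`
#' returns the four atomic meta gender types in their canonical (tie-break)
#' order: transgender male, transgender female, biological male, biological
#' female.
#'
#' @return A character vector of labels in `SCREAMING_SNAKE_CASE`.
#' @export
#' @examples
#' composite_genders()
#' meta_genders()
composite_genders <- function() {
  c("TRANSGENDER_MALE", "TRANSGENDER_FEMALE", "TRANSGENDER_ALL",
    "BIOLOGICAL_MALE", "BIOLOGICAL_FEMALE", "BIOLOGICAL_ALL")
}

#' @rdname composite_genders
#' @export
meta_genders <- function() {
  c("TRANSGENDER_MALE", "TRANSGENDER_FEMALE",
    "BIOLOGICAL_MALE", "BIOLOGICAL_FEMALE")
}

assert_composite <- function(g) {
  bad <- !(g %in% composite_genders())
  if (any(bad)) {
    stop("not a composite gender label: ", paste(g[bad], collapse = ", "),
         call. = FALSE)
  }
  invisible(g)
}

#' Axis and sex of a composite gender label
#'
#' @param g Character vector of composite gender labels.
#' @return `gender_axis()`: `"TRANSGENDER"` or `"BIOLOGICAL"`;
#'   `gender_sex()`: `"MALE"`, `"FEMALE"` or `"ALL"`.
#' @export
gender_axis <- function(g) {
  assert_composite(g)
  sub("_[A-Z]+$", "", g)
}

#' @rdname gender_axis
#' @export
gender_sex <- function(g) {
  assert_composite(g)
  sub("^[A-Z]+_", "", g)
}

#' Logical judgement functions over composite gender labels
#'
#' These predicates encode the internal relations between gender types used
#' by the summarizer's relation inference:
#' \describe{
#'   \item{`split_judgement(g)`}{`TRUE` iff `g` can be split, i.e. it is an
#'     `*_ALL` label.}
#'   \item{`sub_judgement(g1, g2)`}{`TRUE` iff `g1` is a subordinate gender of
#'     `g2`: same axis, `g2` the `*_ALL` of that axis, `g1` a single sex.}
#'   \item{`super_judgement(g1, g2)`}{`TRUE` iff `g1` is a superior gender of
#'     `g2`; the exact converse of `sub_judgement`.}
#'   \item{`reverse_judgement(g1, g2)`}{`TRUE` iff the labels differ.}
#'   \item{`similar_judgement(g1, g2)`}{`TRUE` iff both labels lie on the same
#'     axis (both transgender or both biological).}
#' }
#'
#' All predicates are vectorized over their arguments.
#'
#' @param g,g1,g2 Composite gender labels (see [composite_genders()]).
#' @return A logical vector.
#' @export
#' @examples
#' split_judgement("TRANSGENDER_ALL")                        # TRUE
#' sub_judgement("TRANSGENDER_MALE", "TRANSGENDER_ALL")      # TRUE
#' similar_judgement("TRANSGENDER_ALL", "BIOLOGICAL_MALE")   # FALSE
split_judgement <- function(g) {
  gender_sex(g) == "ALL"
}

#' @rdname split_judgement
#' @export
sub_judgement <- function(g1, g2) {
  gender_axis(g1) == gender_axis(g2) &
    gender_sex(g2) == "ALL" &
    gender_sex(g1) %in% c("MALE", "FEMALE")
}

#' @rdname split_judgement
#' @export
super_judgement <- function(g1, g2) {
  sub_judgement(g2, g1)
}

#' @rdname split_judgement
#' @export
reverse_judgement <- function(g1, g2) {
  assert_composite(g1)
  assert_composite(g2)
  g1 != g2
}

#' @rdname split_judgement
#' @export
similar_judgement <- function(g1, g2) {
  gender_axis(g1) == gender_axis(g2)
}

#' Transformation functions over composite gender labels
#'
#' \describe{
#'   \item{`split_gender(g)`}{Splits an `*_ALL` label into the `MALE` and
#'     `FEMALE` members of its axis, in that order.}
#'   \item{`merge_gender(g1, g2)`}{Merges the two single-sex labels of one
#'     axis into that axis' `*_ALL` label. The contract requires both inputs
#'     non-splittable, on the same axis, and distinct.}
#'   \item{`trans_constrain(g)`}{Transforms a biological gender into the
#'     transgender type implied by reading it as a sex assigned at birth:
#'     the identified gender is the opposite of the assigned sex, so
#'     `BIOLOGICAL_MALE -> TRANSGENDER_FEMALE`,
#'     `BIOLOGICAL_FEMALE -> TRANSGENDER_MALE`, and
#'     `BIOLOGICAL_ALL -> TRANSGENDER_ALL`.}
#' }
#'
#' @param g,g1,g2 Composite gender labels.
#' @return `split_gender()` a length-2 character vector; the others a single
#'   composite label.
#' @export
#' @examples
#' split_gender("TRANSGENDER_ALL")
#' merge_gender("BIOLOGICAL_MALE", "BIOLOGICAL_FEMALE")
#' trans_constrain("BIOLOGICAL_FEMALE")
split_gender <- function(g) {
  if (!split_judgement(g)) {
    stop("cannot split non-splittable gender '", g, "'", call. = FALSE)
  }
  axis <- gender_axis(g)
  c(paste0(axis, "_MALE"), paste0(axis, "_FEMALE"))
}

#' @rdname split_gender
#' @export
merge_gender <- function(g1, g2) {
  if (split_judgement(g1) || split_judgement(g2)) {
    stop("merge requires non-splittable inputs, got '", g1, "', '", g2, "'",
         call. = FALSE)
  }
  if (!similar_judgement(g1, g2)) {
    stop("merge requires same-axis inputs, got '", g1, "', '", g2, "'",
         call. = FALSE)
  }
  if (!reverse_judgement(g1, g2)) {
    stop("merge requires distinct inputs, got '", g1, "' twice", call. = FALSE)
  }
  paste0(gender_axis(g1), "_ALL")
}

#' @rdname split_gender
#' @export
trans_constrain <- function(g) {
  if (gender_axis(g) != "BIOLOGICAL") {
    stop("trans_constrain applies to biological gender only, got '", g, "'",
         call. = FALSE)
  }
  flipped <- switch(gender_sex(g), MALE = "FEMALE", FEMALE = "MALE", ALL = "ALL")
  paste0("TRANSGENDER_", flipped)
}

#' Construct a gender requirement type
#'
#' A `gender_type` holds the transgender and biological components of one of
#' the 13 model types. Components take values `"NONE"`, `"MALE"`, `"FEMALE"`
#' or `"ALL"`; they may not both be `"NONE"`.
#'
#' @param transgender,biological Component values.
#' @return An object of class `gender_type`.
#' @export
#' @examples
#' gender_type("MALE", "NONE")           # Transgender Male
#' gender_type("NONE", "ALL")            # Biological
gender_type <- function(transgender = "NONE", biological = "NONE") {
  comp <- c("NONE", "MALE", "FEMALE", "ALL")
  stopifnot(transgender %in% comp, biological %in% comp)
  if (transgender == "NONE" && biological == "NONE") {
    stop("a gender type needs at least one non-NONE component", call. = FALSE)
  }
  structure(list(transgender = transgender, biological = biological),
            class = "gender_type")
}

render_component <- function(axis, sex) {
  paste(
    if (axis == "TRANSGENDER") "Transgender" else "Biological",
    switch(sex, MALE = "Male", FEMALE = "Female", ALL = "All")
  )
}

#' Render a gender type as its model label
#'
#' All purely biological types collapse to the single label `"Biological"`;
#' otherwise labels read e.g. `"Transgender All, Biological Male"`, exactly
#' as serialized by the model.
#'
#' @param g A `gender_type`.
#' @return A single string, one of the 13 model labels.
#' @export
gender_label <- function(g) {
  stopifnot(inherits(g, "gender_type"))
  if (g$transgender == "NONE") {
    return("Biological")
  }
  lab <- render_component("TRANSGENDER", g$transgender)
  if (g$biological != "NONE") {
    lab <- paste0(lab, ", ", render_component("BIOLOGICAL", g$biological))
  }
  lab
}

#' @export
format.gender_type <- function(x, ...) gender_label(x)

#' @export
print.gender_type <- function(x, ...) {
  cat("<gender_type> ", gender_label(x), "\n", sep = "")
  invisible(x)
}

#' All 13 renderable gender model labels
#'
#' @return Character vector of the 13 labels, `"Biological"` first.
#' @export
gender_model_labels <- function() {
  tg <- c("MALE", "FEMALE", "ALL")
  bio <- c("NONE", "MALE", "FEMALE", "ALL")
  labs <- "Biological"
  for (t in tg) {
    for (b in bio) {
      labs <- c(labs, gender_label(gender_type(t, b)))
    }
  }
  labs
}

#' Compose a gender type from a set of kept meta gender types
#'
#' The meta genders on each axis are merged pairwise (both sexes present on
#' an axis merge to `ALL` via [merge_gender()]); the resulting component pair
#' is the trial's summary gender type. A set with no transgender member
#' yields the collapsed `"Biological"` type, its biological component still
#' carrying the underlying sex evidence.
#'
#' @param kept Character vector (a set) of meta gender types.
#' @return A `gender_type`.
#' @export
#' @examples
#' gender_label(compose_label(c("TRANSGENDER_MALE", "TRANSGENDER_FEMALE",
#'                              "BIOLOGICAL_MALE", "BIOLOGICAL_FEMALE")))
compose_label <- function(kept) {
  kept <- unique(kept)
  if (length(kept) == 0) {
    stop("cannot compose a gender type from no evidence", call. = FALSE)
  }
  assert_composite(kept)
  if (any(gender_sex(kept) == "ALL")) {
    stop("compose_label expects meta gender types, got an *_ALL label",
         call. = FALSE)
  }
  axis_component <- function(axis) {
    sexes <- gender_sex(kept[gender_axis(kept) == axis])
    if (length(sexes) == 0) {
      "NONE"
    } else if (length(sexes) == 2) {
      # both sexes present: pairwise merge to the axis' ALL
      gender_sex(merge_gender(paste0(axis, "_", sexes[1]),
                              paste0(axis, "_", sexes[2])))
    } else {
      sexes
    }
  }
  gender_type(axis_component("TRANSGENDER"), axis_component("BIOLOGICAL"))
}

#' Map a gender type to its conventional registry option
#'
#' Registries record sex eligibility as `Male`, `Female` or `All`. The model
#' maps each of its 13 types back onto this conventional space. Under the
#' default identity mapping a transgender component counts as the identified
#' gender (a transgender-female requirement maps to `FEMALE`); under
#' `by = "assigned"` it counts as the sex assigned at birth instead. The
#' collapsed `"Biological"` type uses its underlying sex component.
#'
#' @param g A `gender_type`.
#' @param by `"identity"` (default) or `"assigned"`.
#' @return One of `"MALE"`, `"FEMALE"`, `"ALL"`.
#' @export
#' @examples
#' to_conventional(gender_type("FEMALE", "NONE"))  # "FEMALE"
#' to_conventional(gender_type("ALL", "ALL"))      # "ALL"
to_conventional <- function(g, by = c("identity", "assigned")) {
  stopifnot(inherits(g, "gender_type"))
  by <- match.arg(by)
  sexes_of <- function(comp, flip = FALSE) {
    if (comp == "NONE") return(character(0))
    if (comp == "ALL") return(c("MALE", "FEMALE"))
    if (flip) {
      if (comp == "MALE") "FEMALE" else "MALE"
    } else {
      comp
    }
  }
  sexes <- unique(c(
    sexes_of(g$transgender, flip = (by == "assigned")),
    sexes_of(g$biological)
  ))
  if (length(sexes) > 1) "ALL" else sexes
}
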