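# Controlled vocabulary: event types, behaviors, body parts, lateralities,
# qualifier vocabularies.  The default schema carries the eleven ictal event
# types of the encoding hierarchy; labels are normalized snake_case
# identifiers with a display-name map.

#' Normalize a display string to a snake_case identifier
#'
#' Lowercases, drops apostrophes, and collapses every other non-alphanumeric
#' run to a single underscore. Used to derive stable identifiers from the
#' human-readable vocabulary strings.
#'
#' @param x character vector of display strings.
#' @return character vector of identifiers.
#' @examples
#' to_identifier("Figure-of-4")          # "figure_of_4"
#' to_identifier("Politician's fist")    # "politicians_fist"
#' @export
to_identifier <- function(x) {
  x <- gsub("'", "", x)
  x <- gsub("[^A-Za-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  tolower(x)
}

.behavior_def <- function(display, body_parts = FALSE, qualifiers = character(0)) {
  list(
    label = to_identifier(display),
    display = display,
    body_parts = isTRUE(body_parts),
    qualifiers = as.character(qualifiers)
  )
}

.event_type_def <- function(id, display, behaviors) {
  labels <- vapply(behaviors, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    behaviors <- behaviors[!duplicated(labels)]
    labels <- labels[!duplicated(labels)]
  }
  names(behaviors) <- labels
  list(id = id, display = display, behaviors = behaviors)
}

.default_qualifier_vocabularies <- function() {
  list(
    forced = c("true", "false"),
    resisted_eye_opening = c("true", "false"),
    hand_posture = c("politicians_fist", "cup", "extended_hand", "pointing",
                     "pincer", "fist"),
    fall_control = c("fully_controlled", "partially_controlled",
                     "uncontrolled", "unknown"),
    position = c("supine", "prone", "lateral", "sitting", "standing")
  )
}

#' Body-part identifiers of the default schema
#' @return character vector of body-part identifiers.
#' @export
default_body_parts <- function() {
  c("head", "face", "eyes", "trunk", "pelvis",
    "upper_limb_proximal", "upper_limb_distal", "hand", "fingers",
    "lower_limb_proximal", "lower_limb_distal", "foot",
    "hemibody", "whole_body")
}

#' Laterality identifiers of the default schema
#' @return character vector: left, right, bilateral, axial.
#' @export
default_lateralities <- function() {
  c("left", "right", "bilateral", "axial")
}

#' The built-in semiology schema
#'
#' Returns the default controlled vocabulary: eleven ictal event types with
#' their behavior vocabularies, the body-part taxonomy, lateralities, and the
#' qualifier vocabularies (forced movement, hand postures, fall control,
#' resisted eye opening, body position). Behavior labels are normalized
#' identifiers; each carries its display string, whether body-part attachment
#' is meaningful, and which qualifiers it admits.
#'
#' The generalized tonic-clonic seizure (gtcs) event type deliberately has an
#' empty behavior vocabulary: the event itself is the finding.
#'
#' @return an object of class `semio_schema`.
#' @examples
#' sch <- default_schema()
#' length(sch$event_types)   # 11
#' @export
default_schema <- function() {
  b <- .behavior_def
  motor_q <- c("hand_posture")
  event_types <- list(
    .event_type_def("simple_motor", "Simple motor", list(
      b("Tonic", TRUE, motor_q), b("Dystonic", TRUE, motor_q),
      b("Clonic", TRUE), b("Myoclonic", TRUE),
      b("Fencer posturing", TRUE), b("Negative myoclonus", TRUE),
      b("Atonic", TRUE), b("Atactic", TRUE), b("Apractic", TRUE),
      b("Tremor", TRUE), b("Paralysis", TRUE), b("Epileptic spasms", TRUE),
      b("Figure-of-4", TRUE),
      b("Head turn", TRUE, "forced")
    )),
    .event_type_def("automatisms", "Automatisms", list(
      b("Limb gesticulating/repetitive movements", TRUE),
      b("Limb semi-purposeful movements", TRUE),
      b("Limb raising", TRUE), b("Nose wiping", TRUE), b("Ear plugging", TRUE),
      b("Genital manipulations"), b("Hand-mouthing"), b("Stepping"),
      b("Pedaling"), b("Oral automatisms"), b("Yawning"),
      b("Facial expressions"), b("Spitting"), b("Vomiting"), b("Cough"),
      b("Sneezing"), b("Pelvic thrust"), b("Urinary behavior"),
      b("Defecation"), b("Other")
    )),
    .event_type_def("autonomic", "Autonomic", list(
      b("Hyperventilation"), b("Hypoventilation"), b("Apnea"), b("Dyspnea"),
      b("Stridor"), b("Piloerection"), b("Pallor"), b("Flushing"),
      b("Cyanosis"), b("Sweating"), b("Mydriasis"), b("Miosis"),
      b("Cheyne Stokes breathing"), b("Irregular breathes"), b("Hiccups"),
      b("Salivation"), b("Urine loss"), b("Fecal loss"), b("Other")
    )),
    .event_type_def("eye_movements", "Eye movements", list(
      b("Gaze deviation", FALSE, "forced"), b("Nystagmus"),
      b("Chaotic eye movements"), b("Blinking"), b("Eyelid myoclonus"),
      b("Blepharospasm"), b("Eyelid retraction"),
      b("Eyelid flutter with closed eyes"), b("Eyes open"),
      b("Eyes closed", FALSE, "resisted_eye_opening")
    )),
    .event_type_def("hyperkinetic", "Hyperkinetic", list(
      b("Bimanual bipedal automatisms"), b("Gyratory movement"), b("Rocking")
    )),
    .event_type_def("voice", "Voice phenomena", list(
      b("Non-verbal vocalization without panic behavior"),
      b("Non-verbal vocalization with panic behavior"),
      b("Coherent speech"), b("Panic speech"), b("Cursing"),
      b("Confused speech using comprehensible words"), b("Perseverations"),
      b("Paraphasia"), b("Motor aphasia"), b("Sensory aphasia"),
      b("Sensorimotor aphasia"), b("Naming difficulty"), b("Laughter"),
      b("Crying"), b("Stuttering"), b("Unintelligible language"),
      b("Snoring"), b("Dysarthria"), b("Hoarseness"), b("Other")
    )),
    .event_type_def("dialeptic", "Dialeptic", list(
      b("Completely irresponsive"), b("Partially irresponsive"), b("Amnesia"),
      b("Cessation of activity"), b("Slowing of activity"),
      b("General muscle hypotonia"), b("Exploratory behavior"),
      b("Non-verbal aggressive behavior"), b("Non-verbal panic behavior"),
      b("Agitation"), b("Disoriented behavior"), b("Other")
    )),
    .event_type_def("gtcs", "GTCS", list()),
    .event_type_def("aura", "Aura", list(
      b("Somatosensory"), b("Visual"), b("Auditory"), b("Gustatory"),
      b("Olfactory"), b("Vertiginous"), b("Autonomic/visceral"),
      b("Experiential"), b("Cephalic"), b("Other")
    )),
    .event_type_def("other", "Other", list(
      b("Vigilance change"), b("Patient's position change", FALSE, "position"),
      b("Walking"), b("Observer's behavior change"),
      b("Patient moves out of the video-camera field"),
      b("Head nodding"), b("Side-to-side head movements"),
      b("Unspecified head movements"),
      b("Unspecified movements of trunk/face/limbs", TRUE),
      b("Falling", FALSE, "fall_control"), b("Eating"), b("Drinking"),
      b("Physical trauma", TRUE),
      b("Periodic limb movements of sleep", TRUE), b("Chorea", TRUE),
      b("Athetosis", TRUE), b("Akathisia"), b("Tics", TRUE), b("Balismus", TRUE),
      b("Unspecified dyskinesia", TRUE), b("Unspecified dystonia", TRUE),
      b("Body part shaking", TRUE), b("Pelvic thrust"), b("Other")
    )),
    .event_type_def("trigger", "Trigger", list(
      b("Visual"), b("Music"), b("Auditory non-musical"), b("Tactile"),
      b("Startle"), b("Eating"), b("Drinking"), b("Other")
    ))
  )
  names(event_types) <- vapply(event_types, `[[`, "", "id")
  new_semio_schema(
    version = "1.0",
    event_types = event_types,
    body_parts = default_body_parts(),
    lateralities = default_lateralities(),
    qualifier_vocabularies = .default_qualifier_vocabularies()
  )
}

#' Construct and check a semiology schema
#'
#' Low-level constructor enforcing the schema invariants: unique event-type
#' identifiers, unique behavior labels within each event type, and every
#' qualifier referenced by a behavior definition resolving to a qualifier
#' vocabulary.
#'
#' @param version schema version string.
#' @param event_types named ordered list of event-type definitions.
#' @param body_parts character vector of body-part identifiers.
#' @param lateralities character vector of laterality identifiers.
#' @param qualifier_vocabularies named list mapping qualifier name to its
#'   allowed values (character vectors; booleans are `c("true","false")`).
#' @return an object of class `semio_schema`.
#' @export
new_semio_schema <- function(version, event_types, body_parts, lateralities,
                             qualifier_vocabularies) {
  ids <- vapply(event_types, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(schema_error(sprintf("duplicate event type id(s): %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", "))))
  }
  names(event_types) <- ids
  for (et in event_types) {
    labels <- vapply(et$behaviors, `[[`, "", "label")
    if (anyDuplicated(labels)) {
      stop(schema_error(sprintf("duplicate behavior label(s) under '%s': %s",
                                et$id, paste(unique(labels[duplicated(labels)]),
                                             collapse = ", "))))
    }
    for (bd in et$behaviors) {
      missing_q <- setdiff(bd$qualifiers, names(qualifier_vocabularies))
      if (length(missing_q)) {
        stop(schema_error(sprintf(
          "behavior '%s' under '%s' references unknown qualifier(s): %s",
          bd$label, et$id, paste(missing_q, collapse = ", "))))
      }
    }
  }
  structure(
    list(version = as.character(version),
         event_types = event_types,
         body_parts = as.character(body_parts),
         lateralities = as.character(lateralities),
         qualifier_vocabularies = qualifier_vocabularies),
    class = "semio_schema"
  )
}

schema_error <- function(message) {
  structure(class = c("semiology_schema_error", "error", "condition"),
            list(message = message, call = NULL))
}

#' Event-type identifiers of a schema
#' @param schema a `semio_schema`.
#' @return character vector of event-type ids, in schema order.
#' @export
event_types <- function(schema) {
  stopifnot(inherits(schema, "semio_schema"))
  unname(vapply(schema$event_types, `[[`, "", "id"))
}

#' Behavior labels defined under an event type
#' @param schema a `semio_schema`.
#' @param event_type event-type identifier.
#' @return character vector of behavior labels (possibly empty).
#' @export
behaviors_of <- function(schema, event_type) {
  stopifnot(inherits(schema, "semio_schema"))
  et <- schema$event_types[[event_type]]
  if (is.null(et)) {
    stop(schema_error(sprintf("unknown event type: '%s'", event_type)))
  }
  unname(vapply(et$behaviors, `[[`, "", "label"))
}

#' Does a behavior label belong to an event type's vocabulary?
#'
#' Returns `TRUE` when the label is in the event type's vocabulary, when it is
#' the literal free-text label `"other"` (admitted under every event type,
#' with a mandatory note enforced at episode validation), or when the event
#' type is the catch-all `other` category, which accepts free-text labels.
#' An unknown event type is a schema error, distinct from an unknown behavior.
#'
#' @param schema a `semio_schema`.
#' @param event_type event-type identifier.
#' @param behavior_label behavior label to test.
#' @return logical scalar.
#' @examples
#' sch <- default_schema()
#' validate_term(sch, "simple_motor", "tonic")   # TRUE
#' validate_term(sch, "gtcs", "tonic")           # FALSE
#' @export
validate_term <- function(schema, event_type, behavior_label) {
  vocab <- behaviors_of(schema, event_type)  # errors on unknown event type
  behavior_label %in% vocab ||
    identical(behavior_label, "other") ||
    identical(event_type, "other")
}

#' Write a schema to a JSON document
#'
#' @param schema a `semio_schema`.
#' @param path file path; if `NULL` the JSON text is returned invisibly.
#' @return the JSON text, invisibly.
#' @export
write_schema <- function(schema, path = NULL) {
  stopifnot(inherits(schema, "semio_schema"))
  doc <- list(
    version = schema$version,
    event_types = lapply(unname(schema$event_types), function(et) {
      list(id = et$id, display = et$display,
           behaviors = lapply(unname(et$behaviors), function(bd) {
             list(label = bd$label, display = bd$display,
                  body_parts = bd$body_parts,
                  qualifiers = I(bd$qualifiers))
           }))
    }),
    body_parts = schema$body_parts,
    lateralities = schema$lateralities,
    qualifier_vocabularies = lapply(schema$qualifier_vocabularies, I)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(as.character(txt))
}

#' Load a schema from a JSON document
#'
#' Round-trip stable with [write_schema()]: loading a written default schema
#' is identical to the built-in one. Duplicate identifiers and dangling
#' qualifier references are rejected. Documents may extend the default
#' vocabulary (additional event types, behaviors, qualifiers).
#'
#' @param path path to a schema JSON file, or a JSON string.
#' @return an object of class `semio_schema`.
#' @export
load_schema <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("version", "event_types", "body_parts", "lateralities",
            "qualifier_vocabularies")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop(schema_error(sprintf("schema document lacks field(s): %s",
                              paste(missing, collapse = ", "))))
  }
  event_types <- lapply(doc$event_types, function(et) {
    behaviors <- lapply(et$behaviors, function(bd) {
      list(label = as.character(bd$label),
           display = as.character(bd$display),
           body_parts = isTRUE(bd$body_parts),
           qualifiers = as.character(unlist(bd$qualifiers)))
    })
    names(behaviors) <- vapply(behaviors, `[[`, "", "label")
    list(id = as.character(et$id), display = as.character(et$display),
         behaviors = behaviors)
  })
  new_semio_schema(
    version = doc$version,
    event_types = event_types,
    body_parts = unlist(doc$body_parts),
    lateralities = unlist(doc$lateralities),
    qualifier_vocabularies = lapply(doc$qualifier_vocabularies,
                                    function(v) as.character(unlist(v)))
  )
}

#' @export
print.semio_schema <- function(x, ...) {
  cat(sprintf("<semio_schema v%s: %d event types, %d body parts>\n",
              x$version, length(x$event_types), length(x$body_parts)))
  for (et in x$event_types) {
    cat(sprintf("  %-14s %d behaviors\n", et$id, length(et$behaviors)))
  }
  invisible(x)
}
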