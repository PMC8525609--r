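# Controlled vocabulary: cardinality, Table-of-terms content, round trip.

test_that("default schema has exactly eleven event types in canonical order", {
  sch <- default_schema()
  expect_length(sch$event_types, 11L)
  expect_identical(
    event_types(sch),
    c("simple_motor", "automatisms", "autonomic", "eye_movements",
      "hyperkinetic", "voice", "dialeptic", "gtcs", "aura", "other",
      "trigger"))
})

test_that("behavior vocabularies contain every standard term", {
  sch <- default_schema()
  # transcribed behavioral-category fixture, one display string per term
  fixture <- list(
    simple_motor = c("Tonic", "Dystonic", "Clonic", "Myoclonic",
                     "Fencer posturing", "Negative myoclonus", "Atonic",
                     "Atactic", "Apractic", "Tremor", "Paralysis",
                     "Epileptic spasms", "Figure-of-4"),
    automatisms = c("Limb gesticulating/repetitive movements",
                    "Limb semi-purposeful movements", "Limb raising",
                    "Nose wiping", "Ear plugging", "Genital manipulations",
                    "Hand-mouthing", "Stepping", "Pedaling",
                    "Oral automatisms", "Yawning", "Facial expressions",
                    "Spitting", "Vomiting", "Cough", "Sneezing",
                    "Pelvic thrust", "Urinary behavior", "Defecation",
                    "Other"),
    autonomic = c("Hyperventilation", "Hypoventilation", "Apnea", "Dyspnea",
                  "Stridor", "Piloerection", "Pallor", "Flushing", "Cyanosis",
                  "Sweating", "Mydriasis", "Miosis", "Cheyne Stokes breathing",
                  "Irregular breathes", "Hiccups", "Salivation", "Urine loss",
                  "Fecal loss", "Other"),
    eye_movements = c("Gaze deviation", "Nystagmus", "Chaotic eye movements",
                      "Blinking", "Eyelid myoclonus", "Blepharospasm",
                      "Eyelid retraction", "Eyelid flutter with closed eyes",
                      "Eyes open", "Eyes closed"),
    hyperkinetic = c("Bimanual bipedal automatisms", "Gyratory movement",
                     "Rocking"),
    voice = c("Non-verbal vocalization without panic behavior",
              "Non-verbal vocalization with panic behavior",
              "Coherent speech", "Panic speech", "Cursing",
              "Confused speech using comprehensible words", "Perseverations",
              "Paraphasia", "Motor aphasia", "Sensory aphasia",
              "Sensorimotor aphasia", "Naming difficulty", "Laughter",
              "Crying", "Stuttering", "Unintelligible language", "Snoring",
              "Dysarthria", "Hoarseness", "Other"),
    dialeptic = c("Completely irresponsive", "Partially irresponsive",
                  "Amnesia", "Cessation of activity", "Slowing of activity",
                  "General muscle hypotonia", "Exploratory behavior",
                  "Non-verbal aggressive behavior", "Non-verbal panic behavior",
                  "Agitation", "Disoriented behavior", "Other"),
    gtcs = character(0),
    aura = c("Somatosensory", "Visual", "Auditory", "Gustatory", "Olfactory",
             "Vertiginous", "Autonomic/visceral", "Experiential", "Cephalic",
             "Other"),
    other = c("Vigilance change", "Patient's position change", "Walking",
              "Observer's behavior change",
              "Patient moves out of the video-camera field", "Head nodding",
              "Side-to-side head movements", "Unspecified head movements",
              "Unspecified movements of trunk/face/limbs", "Falling",
              "Eating", "Drinking", "Physical trauma",
              "Periodic limb movements of sleep", "Chorea", "Athetosis",
              "Akathisia", "Tics", "Balismus", "Unspecified dyskinesia",
              "Unspecified dystonia", "Body part shaking", "Pelvic thrust",
              "Other"),
    trigger = c("Visual", "Music", "Auditory non-musical", "Tactile",
                "Startle", "Eating", "Drinking", "Other")
  )
  for (et in names(fixture)) {
    expect_true(all(to_identifier(fixture[[et]]) %in% behaviors_of(sch, et)),
                label = sprintf("all standard '%s' terms present", et))
  }
  # GTCS stays a valid, selectable event type with an empty vocabulary
  expect_length(behaviors_of(sch, "gtcs"), 0L)
  # the same label may recur under different event types
  expect_true("pelvic_thrust" %in% behaviors_of(sch, "automatisms"))
  expect_true("pelvic_thrust" %in% behaviors_of(sch, "other"))
  expect_true("fencer_posturing" %in% behaviors_of(sch, "simple_motor"))
})

test_that("hand postures, fall control, and position vocabularies exist", {
  qv <- default_schema()$qualifier_vocabularies
  expect_setequal(qv$hand_posture,
                  c("politicians_fist", "cup", "extended_hand", "pointing",
                    "pincer", "fist"))
  expect_setequal(qv$fall_control,
                  c("fully_controlled", "partially_controlled",
                    "uncontrolled", "unknown"))
  expect_true("prone" %in% qv$position)
})

test_that("validate_term distinguishes vocabulary, free text, and errors", {
  sch <- default_schema()
  expect_true(validate_term(sch, "simple_motor", "tonic"))
  expect_false(validate_term(sch, "gtcs", "tonic"))
  expect_true(validate_term(sch, "hyperkinetic", "rocking"))
  # 'other' free-text label admitted under every event type
  expect_true(validate_term(sch, "simple_motor", "other"))
  # the catch-all event type accepts free text
  expect_true(validate_term(sch, "other", "leg_movements_under_blanket"))
  expect_false(validate_term(sch, "simple_motor", "no_such_behavior"))
  # unknown event type is a schema error, not FALSE
  expect_error(validate_term(sch, "nonexistent", "tonic"),
               class = "semiology_schema_error")
})

test_that("schema write/load round-trips and rejects malformed documents", {
  sch <- default_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, path)
  expect_identical(load_schema(path), sch)

  # duplicate event-type ids rejected
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$event_types[[12]] <- doc$event_types[[1]]
  dup <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), dup)
  expect_error(load_schema(dup), class = "semiology_schema_error")

  # a 12th custom event type loads (extensibility)
  doc$event_types[[12]]$id <- "custom"
  doc$event_types[[12]]$display <- "Custom"
  ext <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), ext)
  expect_length(load_schema(ext)$event_types, 12L)

  # dangling qualifier reference rejected
  doc2 <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc2$event_types[[1]]$behaviors[[1]]$qualifiers <- list("no_such_qualifier")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE), bad)
  expect_error(load_schema(bad), class = "semiology_schema_error")
})
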