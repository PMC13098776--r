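test_that("stays in one encounter merge on sub-24-h gaps only", {
  # two stays, gap 20 h -> merged
  a <- make_admissions(c(0, 68), c(48, 100))
  a$encounter_id <- "E1"; a$patient_id <- "p1"
  m <- merge_admissions(a)
  expect_equal(nrow(m), 1)
  expect_equal(m$picu_start, 0)
  expect_equal(m$picu_end, 100)
  expect_equal(m$admission_id, "A1")

  # gap 30 h -> kept apart
  b <- make_admissions(c(0, 78), c(48, 100))
  b$encounter_id <- "E1"; b$patient_id <- "p1"
  expect_equal(nrow(merge_admissions(b)), 2)

  # three stays, gaps 10 h and 40 h -> first two merge (pairwise scan)
  c3 <- make_admissions(c(0, 58, 150), c(48, 110, 170))
  c3$encounter_id <- "E1"; c3$patient_id <- "p1"
  m3 <- merge_admissions(c3)
  expect_equal(nrow(m3), 2)
  expect_equal(m3$picu_end[1], 110)

  # different encounters never merge, whatever the gap
  d <- make_admissions(c(0, 50), c(48, 90))
  expect_equal(nrow(merge_admissions(d)), 2)
})

test_that("merging rejects overlapping stays and is idempotent", {
  bad <- make_admissions(c(0, 40), c(48, 90))
  bad$encounter_id <- "E1"
  expect_error(merge_admissions(bad), "overlap")

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    starts <- sort(runif(n, 0, 400))
    ends <- starts + runif(n, 5, 60)
    starts[-1] <- pmax(starts[-1], ends[-n])  # non-overlapping
    a <- make_admissions(starts, ends)
    a$encounter_id <- sample(c("E1", "E2"), n, replace = TRUE)
    a <- a[order(a$encounter_id, a$picu_start), ]
    ok <- tryCatch({merge_admissions(a); TRUE}, error = function(e) FALSE)
    if (!ok) next
    m1 <- merge_admissions(a)
    expect_identical(merge_admissions(m1), m1)
  }
})

test_that("inclusion filter enforces the 24-h stay and 0-24-y age bounds", {
  a <- make_admissions(rep(0, 5), c(23.9, 48, 48, 48, 30))
  a$age_years <- c(5, 24.0, 25, -1, 10)
  out <- apply_inclusion(a)
  # 23.9-h stay out; age 24.0 retained (inclusive 0-24 y); 25 and -1 out
  expect_equal(out$admission_id, c("A2", "A5"))
  flow <- attr(out, "flow")
  expect_equal(flow$input, 5)
  expect_equal(flow$excluded_duration, 1)
  expect_equal(flow$excluded_age, 2)
  expect_equal(flow$retained, 2)
})

test_that("UEI confirmation applies the 48-h persistence rule", {
  it <- data.frame(admission_id = c("A1", "A2", "A3", "A4"),
                   event_time = c(0, 0, 0, 0),
                   extubation_time = c(50, 12, 48, NA))
  out <- classify_uei(it)
  expect_equal(out$confirmed, c(TRUE, FALSE, TRUE, TRUE))  # 48 h exactly: UEI
  expect_equal(out$ongoing_at_end, c(FALSE, FALSE, FALSE, TRUE))

  bad <- data.frame(admission_id = "A1", event_time = 10, extubation_time = 5)
  expect_error(classify_uei(bad), "precedes")

  pl <- data.frame(admission_id = "A1", event_time = 0,
                   extubation_time = 100, planned = TRUE)
  expect_false(classify_uei(pl)$confirmed)
})

test_that("event deduplication keeps the first of each 8-h trajectory", {
  # CPR then ECMO 1 h later: only the CPR survives
  ev <- data.frame(admission_id = "A1", event_type = c("CPR", "ECMO"),
                   event_time = c(10, 11))
  expect_equal(deduplicate_events(ev)$event_type, "CPR")

  # 9-h gap: both survive
  ev2 <- data.frame(admission_id = "A1", event_type = "CPR",
                    event_time = c(10, 19))
  expect_equal(nrow(deduplicate_events(ev2)), 2)

  # t, t+5, t+9: anchoring conventions diverge
  ev3 <- data.frame(admission_id = "A1", event_type = "CPR",
                    event_time = c(0, 5, 9))
  expect_equal(deduplicate_events(ev3, anchor = "kept")$event_time, c(0, 9))
  expect_equal(deduplicate_events(ev3, anchor = "raw")$event_time, 0)

  # exactly 8 h apart is not "within 8 hours": both kept
  ev4 <- data.frame(admission_id = "A1", event_type = "CPR",
                    event_time = c(0, 8))
  expect_equal(nrow(deduplicate_events(ev4)), 2)
})

test_that("deduplicated output is a subset with all gaps >= 8 h", {
  set.seed(7)
  for (rep in 1:50) {
    ev <- data.frame(admission_id = sample(c("A1", "A2"), 12, replace = TRUE),
                     event_type = "CPR",
                     event_time = round(runif(12, 0, 60), 2))
    out <- deduplicate_events(ev)
    expect_true(all(out$event_time %in% ev$event_time))
    for (adm in unique(out$admission_id)) {
      tt <- sort(out$event_time[out$admission_id == adm])
      if (length(tt) > 1) expect_true(all(diff(tt) >= 8))
    }
  }
})

test_that("temporal split excludes straddling encounters from validation", {
  a <- make_admissions(c(0, 0, 0), c(100, 100, 100))
  boundary <- 1000
  a$picu_start <- c(500, 1200, 1100)    # dev, val, straddler
  a$picu_end <- a$picu_start + 100
  a$encounter_start <- c(480, 1150, 900)
  sp <- temporal_split(a, boundary)
  expect_equal(sp$development, "A1")
  expect_equal(sp$validation, "A2")
  expect_equal(sp$excluded_straddlers, "A3")
  # three-way partition
  expect_setequal(c(sp$development, sp$validation, sp$excluded_straddlers),
                  a$admission_id)

  # degenerate: everything before the boundary
  sp2 <- temporal_split(a, 1e6)
  expect_length(sp2$validation, 0)
  expect_length(sp2$development, 3)
})

test_that("training samples honour the exclusion windows and horizons", {
  adm <- make_admissions(c(0, 0, 0), c(60, 60, 30))
  ev <- make_events(c("A1", "A2"), c(10, 40))  # A1's only CDE is early
  s <- build_training_samples(adm, ev, seed = 3)

  expect_false("A1" %in% s$admission_id)  # 16-h rule drops the admission
  pos <- s[s$admission_id == "A2", ]
  expect_equal(sort(pos$snapshot_time), c(28, 32, 34, 36, 38, 39))
  expect_true(all(pos$label == 1))

  ctl <- s[s$admission_id == "A3", ]
  expect_equal(nrow(ctl), 1)
  expect_true(ctl$snapshot_time >= 16 && ctl$snapshot_time <= 24)
  expect_true(is.na(ctl$horizon))

  # positive snapshots never precede the PICU start: a horizon reaching
  # back past the stay start is dropped for that event
  ev2 <- make_events("A3", 17)
  s2 <- build_training_samples(adm[3, ], ev2, horizons = c(1, 2, 20),
                               seed = 3)
  expect_equal(sort(s2$snapshot_time), 17 - c(2, 1))
})

test_that("control sampling is reproducible and admission-stable", {
  adm <- make_admissions(c(0, 0, 0), c(60, 80, 100))
  ev <- make_events("Axx", 40)[0, ]
  s1 <- build_training_samples(adm, ev, seed = 5)
  s2 <- build_training_samples(adm, ev, seed = 5)
  expect_identical(s1, s2)
  s3 <- build_training_samples(adm, ev, seed = 6)
  expect_false(identical(s1$snapshot_time, s3$snapshot_time))
  # dropping one admission leaves the others' control times untouched
  s4 <- build_training_samples(adm[-2, ], ev, seed = 5)
  expect_equal(s4$snapshot_time[s4$admission_id == "A3"],
               s1$snapshot_time[s1$admission_id == "A3"])
  # control times are at 1-minute resolution
  expect_true(all(abs(s1$snapshot_time * 60 - round(s1$snapshot_time * 60)) < 1e-9))
})

test_that("confirm_cde composes the UEI, window and dedup rules", {
  adm <- make_admissions(c(0, 0), c(200, 200))
  ev <- data.frame(
    admission_id = c("A1", "A1", "A1", "A2"),
    event_type = c("CPR", "INTUBATION", "INTUBATION", "ECMO"),
    event_time = c(20, 21, 100, 30),
    extubation_time = c(NA, 90, 110, NA))  # 69-h UEI; 10-h elective
  out <- confirm_cde(ev, adm)
  # CPR kept; intubation at 21 confirmed UEI but inside the 8-h lockout of
  # the CPR? gap 1 h -> suppressed; intubation at 100 is elective (10 h)
  expect_equal(out$event_type[out$admission_id == "A1"], "CPR")
  expect_equal(out$event_type[out$admission_id == "A2"], "ECMO")

  bad <- data.frame(admission_id = "A1", event_type = "CPR",
                    event_time = 300, extubation_time = NA)
  expect_error(confirm_cde(bad, adm), "outside")
})
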