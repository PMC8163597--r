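test_that("experience groups follow the printed bins exactly", {
  totals <- c(0, 39, 40, 49, 50, 55, 59, 60, 69, 70, 120)
  expect_equal(
    as.character(assign_group(totals)),
    c("excluded", "excluded", "1", "1", "2", "2", "2", "3", "3", "4", "4")
  )
  expect_error(assign_group(-1), class = "consistr_validation_error")
})

test_that("group assignment partitions students by their own totals", {
  set.seed(31)
  r <- random_restorations(400, n_students = 8)
  a <- group_assignments(r)
  expect_equal(sum(a$total_restorations), nrow(r))
  expect_equal(nrow(a), dplyr::n_distinct(r$student_id))
  # recompute each total independently
  for (s in a$student_id) {
    expect_equal(a$total_restorations[a$student_id == s],
                 sum(r$student_id == s))
  }
})

test_that("singleton group cells collapse to median = min = max", {
  r <- make_restorations(rep(5L, 45),
                         surface = c(rep("occlusal_surface", 3),
                                     rep("smooth_surface", 42)))
  tab <- group_descriptives(r)
  occ <- tab[tab$measure == "surface" & tab$level == "occlusal_surface" &
               tab$group == "1", ]
  expect_equal(occ$median, 3)
  expect_equal(occ$min, 3)
  expect_equal(occ$max, 3)
  smooth <- tab[tab$measure == "surface" & tab$level == "smooth_surface" &
                  tab$group == "1", ]
  expect_equal(smooth$median, 42)
})

test_that("difficulty cells use the sample standard deviation", {
  mk <- function(id, n_diff, n_tot) {
    make_restorations(
      rep(5L, n_tot), student_id = id,
      quadrant = c(rep(1L, n_diff), rep(3L, n_tot - n_diff)),
      tooth = c(rep(6L, n_diff), rep(2L, n_tot - n_diff))
    )
  }
  r <- dplyr::bind_rows(mk("A", 16, 40), mk("B", 24, 40))
  r$restoration_id <- sprintf("R%04d", seq_len(nrow(r)))
  tab <- group_descriptives(r)
  cell <- tab[tab$measure == "difficulty_pct" & tab$group == "1", ]
  expect_equal(cell$mean, 50)            # mean of 40% and 60%
  expect_equal(cell$sd, sd(c(40, 60)))   # n-1 formula
})

test_that("every descriptive cell matches a brute-force per-student tally", {
  set.seed(32)
  r <- random_restorations(700, n_students = 12)
  a <- group_assignments(r)
  tab <- group_descriptives(r)
  groups <- unique(tab$group)
  for (g in groups) {
    students <- if (g == "total") {
      a$student_id[a$group != "excluded"]
    } else {
      a$student_id[as.character(a$group) == g]
    }
    for (surf in surface_classes()) {
      counts <- vapply(students, function(s) {
        sum(r$student_id == s & r$surface == surf)
      }, 1)
      cell <- tab[tab$group == g & tab$measure == "surface" &
                    tab$level == surf, ]
      expect_equal(cell$median, median(counts))
      expect_equal(cell$min, min(counts))
      expect_equal(cell$max, max(counts))
    }
    for (q in 1:4) {
      counts <- vapply(students, function(s) {
        sum(r$student_id == s & r$quadrant == q)
      }, 1)
      cell <- tab[tab$group == g & tab$measure == "quadrant" &
                    tab$level == as.character(q), ]
      expect_equal(cell$median, median(counts))
    }
    n_cell <- tab[tab$group == g & tab$measure == "students", ]
    expect_equal(n_cell$n_students, length(students))
  }
  # per-student conservation: surface counts and quadrant counts both sum to
  # the student's total
  for (s in a$student_id) {
    sub <- r[r$student_id == s, ]
    expect_equal(sum(table(factor(sub$surface, surface_classes()))), nrow(sub))
    expect_equal(sum(table(factor(sub$quadrant, 1:4))), nrow(sub))
  }
})

test_that("excluded students appear in no group column by default", {
  r <- dplyr::bind_rows(
    make_restorations(rep(5L, 45), student_id = "A"),
    make_restorations(rep(5L, 10), student_id = "B")
  )
  r$restoration_id <- sprintf("R%04d", seq_len(nrow(r)))
  tab <- group_descriptives(r)
  expect_equal(tab$n_students[tab$measure == "students" & tab$group == "total"], 1L)
  tab2 <- group_descriptives(r, include_excluded_in_total = TRUE)
  expect_equal(tab2$n_students[tab2$measure == "students" & tab2$group == "total"], 2L)
  only_small <- make_restorations(rep(5L, 10))
  expect_error(group_descriptives(only_small), class = "consistr_empty_error")
})
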