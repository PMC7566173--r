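test_that("segment displacement follows the 48/tan(angle) trigonometry", {
  h <- SEGMENT_HEIGHT
  expect_identical(segment_dx(90), 0)
  expect_equal(segment_dx(45), h, tolerance = 1e-12)
  expect_equal(segment_dx(30), h * sqrt(3), tolerance = 1e-12)
  expect_equal(segment_dx(135), -h, tolerance = 1e-12)
  expect_equal(segment_dx(150), -h * sqrt(3), tolerance = 1e-12)
  # generated segments obey the same identity
  co <- generate_course(50, seed = 4, x_bounds = c(0, 1000), start_x = 500)
  expect_equal(co$segments$end_x - co$segments$start_x,
               segment_dx(co$segments$angle_deg), tolerance = 1e-9)
  expect_true(all(co$segments$height == 48))
})

test_that("course generation is deterministic, continuous and bounded", {
  a <- generate_course(25, seed = 7)
  b <- generate_course(25, seed = 7)
  expect_identical(a$segments$angle_deg, b$segments$angle_deg)
  expect_identical(a$breaks_x, b$breaks_x)
  # continuity at junctions
  n <- nrow(a$segments)
  expect_equal(a$segments$end_x[-n], a$segments$start_x[-1])
  # every junction within bounds
  expect_true(all(a$breaks_x >= a$x_bounds[1] & a$breaks_x <= a$x_bounds[2]))
  # generation does not perturb the caller's RNG stream when seeded
  set.seed(123); u1 <- runif(1)
  set.seed(123); invisible(generate_course(10, seed = 99)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("generation rejects impossible requests", {
  expect_error(generate_course(5, seed = 1, x_bounds = c(100, 200),
                               start_x = 50), "outside x_bounds")
  # only steep-right angles allowed but no room to move right
  expect_error(generate_course(5, seed = 1, x_bounds = c(40, 100),
                               start_x = 50, angles = 30), "unsatisfiable")
})

test_that("an all-vertical course is the identity line", {
  co <- straight_course(5, x = 150)
  expect_true(all(co$segments$start_x == co$segments$end_x))
  ys <- seq(0, 5 * 48, by = 7)
  expect_true(all(line_x_at(co, ys) == 150))
  expect_true(all(optimal_x_at(co, ys) == 150))
  expect_identical(nrow(goals_of(co)), 2L)  # start and end only
})

test_that("line interpolation is linear within segments and exact at junctions", {
  co <- generate_course(4, seed = 1, x_bounds = c(0, 500), start_x = 100,
                        angles = 45)
  # midpoint of a 45-degree segment starting at x = 100
  expect_equal(line_x_at(co, 24), 124, tolerance = 1e-12)
  # junction values equal the shared endpoints
  expect_equal(line_x_at(co, co$breaks_y), co$breaks_x, tolerance = 1e-12)
  # continuity: 1-px steps move x by at most max |cot(angle)|
  co2 <- generate_course(30, seed = 2, x_bounds = c(0, 3000), start_x = 1500)
  ys <- seq(0, course_extent <- 30 * 48 - 1, by = 1)
  expect_true(all(abs(diff(line_x_at(co2, ys))) <= sqrt(3) + 1e-9))
  expect_error(line_x_at(co, -1), "outside course extent")
  expect_error(line_x_at(co, 4 * 48 + 1), "outside course extent")
})

test_that("goals sit on angle-change junctions plus endpoints", {
  # alternating 45/135: every interior junction is a corner
  xs <- 100 + cumsum(c(0, segment_dx(c(45, 135, 45, 135))))
  co <- lineadapt:::new_course(c(45, 135, 45, 135), xs, c(0, 300), 100)
  expect_identical(nrow(goals_of(co)), 5L)
  # with goals on every corner the optimal polyline is the centerline
  ys <- seq(0, 4 * 48, by = 0.5)
  expect_equal(optimal_x_at(co, ys), line_x_at(co, ys), tolerance = 1e-9)
  # single segment: two goals
  co1 <- generate_course(1, seed = 3)
  expect_identical(nrow(goals_of(co1)), 2L)
  # same-angle runs produce no interior goal
  co3 <- lineadapt:::new_course(c(45, 45, 90), 100 + cumsum(c(0, 48, 48, 0)),
                                c(0, 300), 100)
  expect_identical(goals_of(co3)$y, c(0, 96, 144))
  # goal rows are multiples of the segment height
  expect_true(all(goals_of(co)$y %% 48 == 0))
})

test_that("optimal and drawn line agree exactly at every goal", {
  co <- generate_course(40, seed = 11, x_bounds = c(0, 2000), start_x = 1000)
  g <- goals_of(co)
  expect_equal(optimal_x_at(co, g$y), g$x, tolerance = 0)
  expect_equal(line_x_at(co, g$y), g$x, tolerance = 0)
})

test_that("angles are drawn uniformly when bounds never bind", {
  co <- generate_course(10000, seed = 5, x_bounds = c(-1e6, 1e6), start_x = 0)
  freq <- table(co$segments$angle_deg) / 10000
  expect_identical(sort(as.numeric(names(freq))), COURSE_ANGLES)
  expect_true(all(abs(freq - 0.2) <= 0.02))
})

test_that("the on-line band is inclusive at its boundary", {
  co <- straight_course(5, x = 150)
  geom <- vehicle_geometry()   # radius 10, line width 5 -> band 12.5
  expect_true(is_on_line(150, co, 100, geom))
  expect_true(is_on_line(150 + 12.5, co, 100, geom))
  expect_false(is_on_line(150 + 13.5, co, 100, geom))
  expect_error(is_on_line(150, co, 10 * 48 + 1, geom), "outside course extent")
})

test_that("JSON serialization round-trips a course exactly", {
  co <- generate_course(12, seed = 21)
  json <- course_to_json(co)
  back <- course_from_json(json)
  expect_identical(back$segments$angle_deg, co$segments$angle_deg)
  expect_equal(back$breaks_x, co$breaks_x, tolerance = 0)
  expect_equal(goals_of(back), goals_of(co), tolerance = 0)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  course_to_json(co, path)
  expect_equal(course_from_json(path)$breaks_x, co$breaks_x, tolerance = 0)
})
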