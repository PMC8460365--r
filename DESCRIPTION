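Package: skelkit
Title: Repair and Kinematic Resolution of RGB-D Skeleton Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for 18-joint skeleton streams produced by
    RGB-D body trackers in home monitoring and telehealth settings. Implements a
    point-cloud-assisted estimation algorithm that repairs missing joints
    (reported as the (0,0,0) sentinel during self-occlusion) and depth-noisy
    joints using limb-length constraints learned at an initialization frame and
    per-limb segmented point clouds; extracts anatomical joint angles (shoulder,
    hip, elbow, knee, vertebral column) from skeleton coordinates by
    vector-geometric projection; and retargets the angle series onto a
    hierarchical kinematic model exported as BVH motion-capture files. Includes
    a forward-kinematic synthetic motion generator with configurable depth
    noise, joint dropout and capsule point clouds so the whole pipeline is
    testable without a sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
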