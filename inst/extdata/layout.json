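{
  "schema": "smartinsole/layout/1",
  "description": "Synthetic 16-sensor insole layout on a No. 39 EU outline (coordinates in mm; x across the width, y along the length from the heel). Sensor positions are a fixed stand-in table placed by anatomical zone; the source system published zones only.",
  "insole_length": 250.0,
  "insole_width": 85.0,
  "outline": { "shape": "ellipse", "cx": 42.5, "cy": 125.0, "rx": 42.5, "ry": 125.0 },
  "grid": { "pitch": 8.47, "ox": 0.5, "oy": 7.0, "n_cells": 227 },
  "sensors": [
    { "id": "T1", "zone": "phalanges", "x": 40.0, "y": 230.0 },
    { "id": "T2", "zone": "phalanges", "x": 25.0, "y": 222.0 },
    { "id": "T3", "zone": "phalanges", "x": 15.0, "y": 210.0 },
    { "id": "T4", "zone": "phalanges", "x": 60.0, "y": 225.0 },
    { "id": "ME1", "zone": "metatarsals", "x": 14.0, "y": 160.0 },
    { "id": "ME2", "zone": "metatarsals", "x": 30.0, "y": 168.0 },
    { "id": "ME3", "zone": "metatarsals", "x": 45.0, "y": 172.0 },
    { "id": "ME4", "zone": "metatarsals", "x": 58.0, "y": 172.0 },
    { "id": "ME5", "zone": "metatarsals", "x": 70.0, "y": 165.0 },
    { "id": "M1", "zone": "arch", "x": 30.0, "y": 90.0 },
    { "id": "M2", "zone": "arch", "x": 55.0, "y": 95.0 },
    { "id": "M3", "zone": "arch", "x": 32.0, "y": 115.0 },
    { "id": "M4", "zone": "arch", "x": 55.0, "y": 120.0 },
    { "id": "H1", "zone": "calcaneus", "x": 42.0, "y": 26.0 },
    { "id": "H2", "zone": "calcaneus", "x": 28.0, "y": 42.0 },
    { "id": "H3", "zone": "calcaneus", "x": 56.0, "y": 42.0 }
  ]
}
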