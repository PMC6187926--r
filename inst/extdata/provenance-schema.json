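{
  "title": "aggtrap scenario provenance record",
  "required": {
    "package": {},
    "version": {},
    "config": {
      "required": {
        "geometry": {},
        "physical": {},
        "species": {},
        "solver": {},
        "spacing": {}
      }
    },
    "grid": {
      "required": {
        "dims": {},
        "spacing": {},
        "cells": {}
      }
    },
    "metrics": {}
  }
}
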