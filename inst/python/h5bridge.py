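#!/usr/bin/env python
"""Tiny HDF5 <-> CSV shuttle for the R package.

Usage:
  h5bridge.py dump  FILE.h5 OUTDIR name=/dataset/path ...
  h5bridge.py write FILE.h5 INDIR  name=/dataset/path ...

dump: each named dataset found in the file is written to OUTDIR/name.csv
(comma-separated, no header); absent datasets are skipped and reported on
stdout as "missing <name>".

write: each INDIR/name.csv that exists is written to the dataset path as a
float64 array (the design-index dataset is stored as int64).
"""
import sys

import h5py
import numpy as np


def parse_spec(args):
    out = {}
    for a in args:
        name, _, path = a.partition("=")
        out[name] = path
    return out


def main(argv):
    if len(argv) < 4 or argv[0] not in {"dump", "write"}:
        sys.stderr.write(__doc__)
        return 2
    mode, h5file, folder = argv[0], argv[1], argv[2]
    spec = parse_spec(argv[3:])
    if mode == "dump":
        with h5py.File(h5file, "r") as f:
            for name, path in spec.items():
                if path not in f:
                    print(f"missing {name}")
                    continue
                data = np.asarray(f[path])
                if data.ndim == 1:
                    data = data[:, None]
                np.savetxt(f"{folder}/{name}.csv", data, delimiter=",",
                           fmt="%.17g")
                print(f"ok {name} {data.shape[0]} {data.shape[1]}")
    else:
        with h5py.File(h5file, "w") as f:
            for name, path in spec.items():
                try:
                    data = np.loadtxt(f"{folder}/{name}.csv", delimiter=",",
                                      ndmin=2)
                except OSError:
                    continue
                if name == "wss_design":
                    data = data.astype(np.int64)
                if data.shape[1] == 1:
                    data = data[:, 0]
                f.create_dataset(path, data=data)
                print(f"ok {name}")
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
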