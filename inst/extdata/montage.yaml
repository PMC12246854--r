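# Default 2x12-channel prefrontal montage for a wearable continuous-wave
# fNIRS system (24 optodes, 10-20 placement between FpZ-F7-F3-FZ and
# FpZ-F8-F4-FZ). Channel ids follow the transmitter-receiver convention
# "Tx<i>-Rx<j>": transmitters 1-5 / receivers 1-4 sit over the right
# hemisphere, transmitters 6-10 / receivers 5-8 over the left.
#
# SYNTHETIC RECONSTRUCTION: hemisphere and Brodmann-area labels for the 17
# channels that appear in published channel-level reports are taken from
# those reports; the remaining 7 channels complete the 2x12 layout with
# labels interpolated from the same placement rule. Source-detector
# separation is the device-typical 3 cm for every channel.
channels:
  - {channel_id: Tx1-Rx1,  hemisphere: right, brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx1-Rx2,  hemisphere: right, brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx2-Rx2,  hemisphere: right, brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx2-Rx3,  hemisphere: right, brodmann_area: 9,  distance_cm: 3.0}
  - {channel_id: Tx3-Rx1,  hemisphere: right, brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx3-Rx2,  hemisphere: right, brodmann_area: 45, distance_cm: 3.0}
  - {channel_id: Tx3-Rx3,  hemisphere: right, brodmann_area: 9,  distance_cm: 3.0}
  - {channel_id: Tx3-Rx4,  hemisphere: right, brodmann_area: 44, distance_cm: 3.0}
  - {channel_id: Tx4-Rx3,  hemisphere: right, brodmann_area: 47, distance_cm: 3.0}
  - {channel_id: Tx4-Rx4,  hemisphere: right, brodmann_area: 47, distance_cm: 3.0}
  - {channel_id: Tx5-Rx3,  hemisphere: right, brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx5-Rx4,  hemisphere: right, brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx6-Rx5,  hemisphere: left,  brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx6-Rx6,  hemisphere: left,  brodmann_area: 9,  distance_cm: 3.0}
  - {channel_id: Tx7-Rx5,  hemisphere: left,  brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx7-Rx6,  hemisphere: left,  brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx8-Rx5,  hemisphere: left,  brodmann_area: 46, distance_cm: 3.0}
  - {channel_id: Tx8-Rx6,  hemisphere: left,  brodmann_area: 9,  distance_cm: 3.0}
  - {channel_id: Tx8-Rx7,  hemisphere: left,  brodmann_area: 45, distance_cm: 3.0}
  - {channel_id: Tx8-Rx8,  hemisphere: left,  brodmann_area: 44, distance_cm: 3.0}
  - {channel_id: Tx9-Rx6,  hemisphere: left,  brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx9-Rx8,  hemisphere: left,  brodmann_area: 10, distance_cm: 3.0}
  - {channel_id: Tx10-Rx7, hemisphere: left,  brodmann_area: 44, distance_cm: 3.0}
  - {channel_id: Tx10-Rx8, hemisphere: left,  brodmann_area: 47, distance_cm: 3.0}
# Laterality channel pairs (homologous right/left regions). Stored as
# printed in the channel-level reports; orientation (which member is the
# right-hemisphere channel) is resolved against the channel table above.
pairs:
  - [Tx9-Rx8, Tx5-Rx4]
  - [Tx9-Rx6, Tx5-Rx3]
  - [Tx3-Rx1, Tx8-Rx5]
  - [Tx3-Rx2, Tx8-Rx7]
  - [Tx2-Rx3, Tx6-Rx6]
  - [Tx4-Rx4, Tx10-Rx8]
  - [Tx3-Rx4, Tx8-Rx8]
wavelengths_nm: [760, 850]
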