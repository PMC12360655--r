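roi,channel
midline,C1
midline,C2
midline,C3
midline,C4
midline,CP1
midline,CP2
midline,CP3
midline,CP4
midline,CPz
midline,Cz
midline,F1
midline,F2
midline,F3
midline,F4
midline,F5
midline,F6
midline,FC1
midline,FC2
midline,FC3
midline,FC4
midline,FCz
midline,Fz
midline,Iz
midline,O1
midline,O2
midline,Oz
midline,P1
midline,P2
midline,P3
midline,P4
midline,P5
midline,P6
midline,PO3
midline,PO4
midline,PO7
midline,PO8
midline,POz
midline,Pz
left,C1
left,C3
left,C5
left,CP1
left,CP3
left,CP5
left,F1
left,F3
left,F5
left,F7
left,FC1
left,FC3
left,FC5
left,O1
left,P1
left,P3
left,P5
left,P7
left,PO3
left,PO7
right,C2
right,C4
right,C6
right,CP2
right,CP4
right,CP6
right,F2
right,F4
right,F6
right,F8
right,FC2
right,FC4
right,FC6
right,O2
right,P2
right,P4
right,P6
right,P8
right,PO4
right,PO8
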