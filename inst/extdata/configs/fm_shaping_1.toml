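# Freely moving acclimation stage 1
task_kind = "fm_shaping_1"
iti = 0.5
reward_volume_ul = 4.0
response_delay = 0.0

[session_end]
max_rewards = 190
max_duration_min = 90

[schedule]
n_trials = 700
labels = ["go"]
probs = [1.0]
max_consecutive = 700
seed = 1

[epochs.delay]
order = 1
name = "Delay"
trigger = "timer"
value = 3.0
stimulus = "gray"

[epochs.stimulus]
order = 2
name = "Stimulus"
trigger = "timer"
value = 60.0
stimulus = "white_circles"

[contingency.go]
correct_side = "center"
reward_port = "center"
volume_ul = 4.0
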